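## GO enrichment (classic Fisher and the elim decorrelation walk) and
## PCA with loading-set extraction.

#' Build a GO DAG with annotation closure
#'
#' @param edges data.frame (child, parent); the graph must be acyclic,
#'   multiple parents are allowed.
#' @param annotation data.frame (feature, go) of direct annotations.
#' @return a \linkS4class{GODag}; each term's annotated feature set
#'   includes the features of all its descendants (true-path rule).
#' @export
goDag <- function(edges, annotation) {
  terms <- unique(c(edges$child, edges$parent, annotation$go))
  parents <- stats::setNames(vector("list", length(terms)), terms)
  for (i in seq_len(nrow(edges)))
    parents[[edges$child[i]]] <- unique(c(parents[[edges$child[i]]],
                                          edges$parent[i]))
  parents <- lapply(parents, function(p) p %||% character())
  ## topological order (children before parents); cycle check
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (i in seq_len(nrow(edges)))
    children[[edges$parent[i]]] <- c(children[[edges$parent[i]]],
                                     edges$child[i])
  n_unresolved <- lengths(stats::setNames(
    lapply(terms, function(t) children[[t]] %||% character()), terms))
  order_out <- character()
  ready <- terms[n_unresolved == 0]
  cnt <- n_unresolved
  while (length(ready)) {
    t <- ready[1]; ready <- ready[-1]
    order_out <- c(order_out, t)
    for (p in parents[[t]]) {
      cnt[p] <- cnt[p] - 1L
      if (cnt[p] == 0L) ready <- c(ready, p)
    }
  }
  if (length(order_out) != length(terms))
    stop("input error: GO graph contains a cycle")
  ## closure: push features from children up to parents
  ann <- stats::setNames(vector("list", length(terms)), terms)
  for (i in seq_len(nrow(annotation)))
    ann[[annotation$go[i]]] <- c(ann[[annotation$go[i]]],
                                 annotation$feature[i])
  for (t in order_out)       # leaves first
    for (p in parents[[t]])
      ann[[p]] <- c(ann[[p]], ann[[t]])
  ann <- lapply(ann, function(a) sort(unique(a %||% character())))
  ## depth: longest path from a root (roots have depth 0), so reversing
  ## the topological order visits parents before children
  depth <- stats::setNames(integer(length(terms)), terms)
  for (t in rev(order_out))
    for (c_ in children[[t]] %||% character())
      depth[c_] <- max(depth[c_], depth[t] + 1L)
  new("GODag", parents = parents, annotated = ann, depth = depth)
}

setMethod("show", "GODag", function(object) {
  cat("GODag with", length(object@parents), "terms, max depth",
      max(object@depth), "and",
      length(unique(unlist(object@annotated))), "annotated features\n")
})

## One-sided hypergeometric upper-tail p for a term.
hyper_p <- function(k, K, n, N) {
  if (K == 0L || n == 0L) return(1)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Classic Fisher GO enrichment
#'
#' Per term, the one-sided hypergeometric upper-tail probability of the
#' observed overlap between the study set and the term's (closed)
#' annotation, within the universe.
#'
#' @param dag a \linkS4class{GODag}.
#' @param study_set,universe_set feature ID vectors; the study set must
#'   be contained in the universe.
#' @return named numeric vector of p-values over all terms.
#' @export
fisherGO <- function(dag, study_set, universe_set) {
  if (!length(study_set) || !length(universe_set))
    stop("input error: empty study or universe set")
  if (!all(study_set %in% universe_set))
    stop("input error: study set not contained in universe")
  N <- length(unique(universe_set)); n <- length(unique(study_set))
  vapply(dag@annotated, function(a) {
    au <- intersect(a, universe_set)
    hyper_p(length(intersect(au, study_set)), length(au), n, N)
  }, numeric(1))
}

#' GO enrichment with the elim algorithm
#'
#' Terms are processed bottom-up (decreasing longest-path depth from the
#' root; ties in lexicographic term order). When a term's p-value falls
#' below \code{alpha}, its annotated features are removed from all of its
#' ancestors before those are tested, decorrelating parent calls from
#' signal already explained by a child.
#'
#' @inheritParams fisherGO
#' @param alpha elimination threshold (default 0.01).
#' @return named numeric vector of elim-adjusted p-values.
#' @export
elimGO <- function(dag, study_set, universe_set, alpha = 0.01) {
  if (!length(study_set) || !length(universe_set))
    stop("input error: empty study or universe set")
  if (!all(study_set %in% universe_set))
    stop("input error: study set not contained in universe")
  N <- length(unique(universe_set)); n <- length(unique(study_set))
  terms <- names(dag@annotated)
  ord <- terms[order(-dag@depth[terms], terms)]
  eliminated <- stats::setNames(vector("list", length(terms)), terms)
  p <- stats::setNames(numeric(length(terms)), terms)
  ancestors <- ancestor_sets(dag)
  for (t in ord) {
    a <- setdiff(intersect(dag@annotated[[t]], universe_set),
                 eliminated[[t]])
    k <- length(intersect(a, study_set))
    p[t] <- hyper_p(k, length(a), n, N)
    if (p[t] < alpha) {
      for (anc in ancestors[[t]])
        eliminated[[anc]] <- union(eliminated[[anc]], dag@annotated[[t]])
    }
  }
  p
}

## term -> all ancestors (transitive closure over parents).
ancestor_sets <- function(dag) {
  terms <- names(dag@parents)
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- dag@parents[[t]]
    out <- unique(c(ps, unlist(lapply(ps, anc))))
    memo[[t]] <- out
    out
  }
  stats::setNames(lapply(terms, anc), terms)
}

#' PCA of an expression matrix
#'
#' Singular-value decomposition of the row-centered matrix of
#' log-transformed expression (by convention log2(cpm + 1) of orthogroup
#' expression; rows are features, columns samples). The loading sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param expr feature x sample numeric matrix.
#' @param n_components number of components to return (default all).
#' @return list with \code{loadings} (feature x component),
#'   \code{scores} (sample x component) and \code{variance_explained}.
#' @export
pcaLoadings <- function(expr, n_components = NULL) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("input error: need at least 2 samples")
  kmax <- min(dim(expr))
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax)
    stop("input error: n_components exceeds min(dim)")
  xc <- expr - rowMeans(expr)
  sv <- svd(xc)
  ve <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  L <- sv$u[, k, drop = FALSE]
  S <- sv$v[, k, drop = FALSE] %*% diag(sv$d[k], nrow = length(k))
  for (j in seq_along(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  dimnames(L) <- list(rownames(expr), paste0("PC", k))
  dimnames(S) <- list(colnames(expr), paste0("PC", k))
  list(loadings = L, scores = S, variance_explained = ve[k])
}

#' Top and bottom loading sets of one component
#'
#' @param loadings named numeric vector (one component's loadings).
#' @param fraction tail fraction in (0, 0.5); default 0.05.
#' @return list \code{top} (loadings at or above the 1 - fraction
#'   quantile) and \code{bottom} (at or below the fraction quantile);
#'   boundary ties are included, and if ties make the sets overlap the
#'   assignment falls back to disjoint rank-based sets.
#' @export
topLoadingSets <- function(loadings, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must be in (0, 0.5)")
  n <- length(loadings)
  if (n < ceiling(1 / fraction))
    warning("fewer than 1/fraction features; sets of size >= 1 guaranteed")
  hi <- stats::quantile(loadings, 1 - fraction, names = FALSE)
  lo <- stats::quantile(loadings, fraction, names = FALSE)
  top <- names(loadings)[loadings >= hi]
  bottom <- names(loadings)[loadings <= lo]
  if (length(intersect(top, bottom))) {
    ## degenerate ties: enforce disjointness by rank (opposite ends of
    ## one deterministic ordering, so the sets can never meet)
    m <- max(1L, min(round(n * fraction), floor(n / 2)))
    ord <- names(loadings)[order(-loadings, names(loadings))]
    top <- ord[seq_len(m)]
    bottom <- rev(ord)[seq_len(m)]
  }
  if (!length(top)) top <- names(loadings)[which.max(loadings)]
  if (!length(bottom)) bottom <- names(loadings)[which.min(loadings)]
  list(top = sort(top), bottom = sort(bottom))
}
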