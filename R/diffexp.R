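## Self-contained differential-expression engine: CPM, TMM normalization,
## moment-based dispersion estimation with shrinkage, the conditional
## negative-binomial exact test, and Benjamini-Hochberg FDR, plus the two
## drivers used by the pipeline (within-species segment contrasts and
## cross-species orthogroup contrasts).

#' Counts per million
#'
#' @param counts feature x sample matrix (or vector).
#' @param lib_sizes per-sample (effective) library sizes; default column
#'   sums. Must be positive.
#' @return matrix of \code{count / lib_size * 1e6}.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("domain error: zero or negative library size")
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values. The reference sample is the one whose 75th
#' percentile of cpm is closest to the mean 75th percentile. For each
#' sample, M (log2 expression ratio vs the reference) and A (average log2
#' abundance) are computed over features nonzero in both; the top and
#' bottom \code{trim_m} by M and \code{trim_a} by A are trimmed and the
#' factor is 2 to the inverse-variance-weighted mean of the remaining M
#' values. Factors are rescaled to geometric mean 1.
#'
#' @param counts feature x sample matrix; at least 2 samples, each with a
#'   nonzero count.
#' @param lib_sizes raw library sizes; default column sums.
#' @param trim_m,trim_a two-sided trim fractions (defaults 0.30 and 0.05).
#' @return list with \code{factors} and \code{effective_lib_sizes}
#'   (raw size x factor), both named by sample.
#' @export
tmmFactors <- function(counts, lib_sizes = colSums(counts),
                       trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (any(colSums(counts) == 0)) stop("input error: all-zero sample")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib_sizes
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(i)
    2^tmm_pair(counts[, i], counts[, ref], lib_sizes[i], lib_sizes[ref],
               trim_m, trim_a), numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  list(factors = fac,
       effective_lib_sizes = stats::setNames(lib_sizes * fac,
                                             colnames(counts)))
}

## Weighted trimmed mean of M-values of one sample against the reference,
## on the log2 scale.
tmm_pair <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (!length(y)) return(0)
  M <- log2(y / n) - log2(yr / nr)
  A <- (log2(y / n) + log2(yr / nr)) / 2
  if (max(abs(M)) < 1e-6) return(0)
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)  # delta-method var of M
  g <- length(M)
  loM <- floor(g * trim_m) + 1; hiM <- g + 1 - loM
  loA <- floor(g * trim_a) + 1; hiA <- g + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(0)
  sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
}

#' Moment-based dispersion estimation
#'
#' Counts are scaled to a common library size; within each group the
#' method-of-moments dispersion \eqn{(v - m)/m^2} is computed per feature
#' and pooled across groups weighted by degrees of freedom, then shrunk
#' 50 percent toward the median of all per-feature estimates and floored
#' at 1e-4.
#'
#' @param counts feature x sample matrix.
#' @param groups factor/character of sample group labels.
#' @param lib_sizes effective library sizes; default column sums.
#' @return named numeric vector of per-feature dispersions.
#' @export
estimateDispersion <- function(counts, groups,
                               lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  tab <- table(groups)
  if (!any(tab >= 2L))
    stop("configuration error: no group has at least two samples")
  z <- sweep(counts, 2, mean(lib_sizes) / lib_sizes, "*")
  raw <- rep(0, nrow(counts)); wsum <- rep(0, nrow(counts))
  for (g in names(tab)[tab >= 2L]) {
    zg <- z[, groups == g, drop = FALSE]
    m <- rowMeans(zg)
    v <- apply(zg, 1, stats::var)
    ok <- m > 0
    contrib <- rep(0, nrow(counts))
    contrib[ok] <- (v[ok] - m[ok]) / m[ok]^2
    w <- ncol(zg) - 1L
    raw <- raw + ifelse(ok, w * contrib, 0)
    wsum <- wsum + ifelse(ok, w, 0)
  }
  raw <- ifelse(wsum > 0, raw / pmax(wsum, 1), 0)
  med <- stats::median(raw)
  phi <- pmax(0.5 * raw + 0.5 * med, 1e-4)
  stats::setNames(phi, rownames(counts))
}

#' Conditional negative-binomial exact test
#'
#' Counts are scaled to a common effective library size (pseudo-counts,
#' rounded half-to-even). Conditional on the pseudo-count total s, the
#' group-A total follows the law induced by the convolution of NB
#' distributions; the two-sided p-value is the summed probability of all
#' splits no more probable than the observed one. A dispersion of zero
#' reduces the conditional law to Binomial(s, nA/(nA+nB)).
#'
#' @param countsA,countsB per-sample counts of the two groups.
#' @param phi dispersion (>= 0).
#' @param lib_sizesA,lib_sizesB effective library sizes per sample.
#' @param prior_count prior added per sample for the fold-change (0.5).
#' @return list with \code{p_value}, \code{log2fc} (B over A) and
#'   \code{avg_logcpm}.
#' @export
exactNBTest <- function(countsA, countsB, phi,
                        lib_sizesA, lib_sizesB, prior_count = 0.5) {
  if (any(c(countsA, countsB) < 0)) stop("domain error: negative counts")
  if (phi < 0) stop("domain error: negative dispersion")
  nA <- length(countsA); nB <- length(countsB)
  Ns <- c(lib_sizesA, lib_sizesB)
  Nstar <- exp(mean(log(Ns)))
  pseudo <- round(c(countsA, countsB) * Nstar / Ns)   # half-to-even
  yA <- sum(pseudo[seq_len(nA)]); yB <- sum(pseudo) - yA
  s <- yA + yB
  cpA <- (countsA + prior_count) / (lib_sizesA + 2 * prior_count) * 1e6
  cpB <- (countsB + prior_count) / (lib_sizesB + 2 * prior_count) * 1e6
  log2fc <- log2(mean(cpB) / mean(cpA))
  avg_logcpm <- log2(mean(c(cpA, cpB)))
  if (s == 0)
    return(list(p_value = 1, log2fc = log2fc, avg_logcpm = avg_logcpm))
  y <- 0:s
  if (phi == 0) {
    logp <- stats::dbinom(y, s, nA / (nA + nB), log = TRUE)
  } else {
    mu <- s / (nA + nB)
    logp <- stats::dnbinom(y, size = nA / phi, mu = nA * mu, log = TRUE) +
      stats::dnbinom(s - y, size = nB / phi, mu = nB * mu, log = TRUE)
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pobs <- pr[yA + 1L]
  p <- sum(pr[pr <= pobs * (1 + 1e-10)])
  list(p_value = min(p, 1), log2fc = log2fc, avg_logcpm = avg_logcpm)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with enforced monotonicity; q-values are capped
#' at 1 and returned in the input order.
#'
#' @param p_values numeric vector in [0, 1].
#' @return numeric vector of q-values.
#' @export
bhFDR <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("domain error: p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric())
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## Assemble the per-feature test results into the standard DE table.
de_table <- function(feature_id, p, lfc, alc, alpha, fc_threshold) {
  q <- bhFDR(p)
  sig <- q < alpha & abs(lfc) > fc_threshold
  data.frame(feature_id = feature_id, log2fc = lfc, avg_logcpm = alc,
             p_value = p, q_value = q,
             direction = ifelse(!sig, "ns",
                                ifelse(lfc > 0, "up_in_B", "up_in_A")),
             significant = sig, stringsAsFactors = FALSE)
}

## Shared test loop over the rows of a two-group count matrix.
run_exact_tests <- function(counts, grpA, grpB, alpha, fc_threshold,
                            dispersion = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) {
    nf <- tmmFactors(counts[, c(grpA, grpB), drop = FALSE])
    lib_sizes <- nf$effective_lib_sizes
  }
  if (is.null(dispersion)) {
    grp <- c(rep("A", length(grpA)), rep("B", length(grpB)))
    dispersion <- estimateDispersion(counts[, c(grpA, grpB), drop = FALSE],
                                     grp, lib_sizes)
  }
  dispersion <- rep_len(dispersion, nrow(counts))
  res <- vapply(seq_len(nrow(counts)), function(i) {
    r <- exactNBTest(counts[i, grpA], counts[i, grpB], dispersion[i],
                     lib_sizes[grpA], lib_sizes[grpB])
    c(r$p_value, r$log2fc, r$avg_logcpm)
  }, numeric(3))
  de_table(rownames(counts), res[1, ], res[2, ], res[3, ],
           alpha, fc_threshold)
}

#' Differentially expressed features between consecutive segments
#'
#' Within one species, tests each orthogroup (or gene) between the two
#' segments of a developmental transition. Normalization (TMM) is computed
#' on exactly the samples entering the comparison. Direction "up_in_B"
#' means higher in the later segment.
#'
#' @param og_expr an \linkS4class{OGExpression} (one species), or a count
#'   matrix with sample columns named \code{species_segment_rep}.
#' @param segment_pair the two segment labels, earlier first.
#' @param alpha FDR threshold (default 0.01).
#' @param fc_threshold significance requires |log2 fold change| strictly
#'   above this (default 1).
#' @param dispersion optional fixed per-feature dispersion.
#' @return the DE table (one row per feature).
#' @export
degBetweenSegments <- function(og_expr, segment_pair, alpha = 0.01,
                               fc_threshold = 1, dispersion = NULL) {
  stopifnot(length(segment_pair) == 2L)
  cd <- colData(og_expr)
  if (!all(segment_pair %in% cd$segment))
    stop("input error: unknown segment in ",
         paste(segment_pair, collapse = "/"))
  keep <- cd$segment %in% segment_pair
  counts <- assay(og_expr)[, keep, drop = FALSE]
  cd <- cd[keep, ]
  grpA <- rownames(cd)[cd$segment == segment_pair[1]]
  grpB <- rownames(cd)[cd$segment == segment_pair[2]]
  if (length(grpA) < 2L || length(grpB) < 2L)
    stop("both segments need at least two replicates")
  run_exact_tests(counts, grpA, grpB, alpha, fc_threshold, dispersion)
}

#' Differentially expressed orthogroups between species
#'
#' Tests orthogroups between the replicates of two species at the same
#' developmental segment (unpaired). TMM is computed jointly over the two
#' species' samples entering the comparison. Direction "up_in_B" means
#' higher in \code{species_pair[2]}.
#'
#' @param og_expr an \linkS4class{OGExpression} over both species.
#' @param species_pair the two species labels.
#' @param segment the matched segment label.
#' @param og_ids orthogroups to test (typically
#'   \code{\link{sharedOrthogroups}} output); default all rows.
#' @param alpha,fc_threshold significance thresholds (0.01 and 1).
#' @param dispersion optional fixed dispersion.
#' @param tf_flags optional named logical vector (orthogroup ->
#'   transcription-factor flag) used for the TF summary.
#' @return list with \code{results} (DE table) and \code{tf_summary}
#'   (\code{n_tf}, \code{n_deo}, \code{pct_tf} to one decimal), the latter
#'   NULL without \code{tf_flags}.
#' @export
deoBetweenSpecies <- function(og_expr, species_pair, segment,
                              og_ids = NULL, alpha = 0.01,
                              fc_threshold = 1, dispersion = NULL,
                              tf_flags = NULL) {
  stopifnot(length(species_pair) == 2L)
  cd <- colData(og_expr)
  for (s in species_pair)
    if (!any(cd$species == s & cd$segment == segment))
      stop("input error: segment ", segment, " missing in species ", s)
  keep <- cd$species %in% species_pair & cd$segment == segment
  counts <- assay(og_expr)[, keep, drop = FALSE]
  if (!is.null(og_ids)) counts <- counts[og_ids, , drop = FALSE]
  cd <- cd[keep, ]
  grpA <- rownames(cd)[cd$species == species_pair[1]]
  grpB <- rownames(cd)[cd$species == species_pair[2]]
  res <- run_exact_tests(counts, grpA, grpB, alpha, fc_threshold, dispersion)
  tf_summary <- if (!is.null(tf_flags)) tfSummary(res, tf_flags) else NULL
  list(results = res, tf_summary = tf_summary)
}

#' Transcription-factor share of significant orthogroups
#'
#' @param de_results a DE table (from the drivers above).
#' @param tf_flags named logical vector, orthogroup -> TF flag.
#' @return list \code{n_tf}, \code{n_deo}, \code{pct_tf} (percent, one
#'   decimal, rounded half-to-even).
#' @export
tfSummary <- function(de_results, tf_flags) {
  deo <- de_results$feature_id[de_results$significant]
  n_tf <- sum(tf_flags[deo], na.rm = TRUE)
  list(n_tf = n_tf, n_deo = length(deo),
       pct_tf = pct1(n_tf, length(deo)))
}
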