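## Orthogroup-level expression: table parsing, annotation transfer,
## shared-orthogroup restriction, and member-sum aggregation.

#' @describeIn OrthogroupMap-accessors orthogroup IDs.
#' @export
ogIds <- function(map) names(map@membership)

#' Accessors for OrthogroupMap
#'
#' @param map an \linkS4class{OrthogroupMap}.
#' @param og orthogroup ID.
#' @param species optional species label.
#' @name OrthogroupMap-accessors
NULL

#' @describeIn OrthogroupMap-accessors species column labels.
#' @export
ogSpecies <- function(map) map@species

#' @describeIn OrthogroupMap-accessors member transcript IDs of one
#'   orthogroup, for one species or all.
#' @export
ogMembers <- function(map, og, species = NULL) {
  m <- map@membership[[og]]
  if (is.null(m)) stop("unknown orthogroup: ", og)
  if (is.null(species)) m else m[[species]]
}

#' @describeIn OrthogroupMap-accessors copy-number matrix (orthogroup x
#'   species member counts).
#' @export
copyNumber <- function(map) {
  t(vapply(map@membership, function(m) lengths(m)[map@species],
           integer(length(map@species))))
}

#' @describeIn OrthogroupMap-accessors transferred annotation DataFrame
#'   (empty until \code{\link{transferAnnotation}} has run).
#' @export
ogAnnotation <- function(map) map@annotation

setMethod("show", "OrthogroupMap", function(object) {
  cat("OrthogroupMap with", length(object@membership), "orthogroups over",
      length(object@species), "species:",
      paste(object@species, collapse = ", "), "\n")
  if (ncol(object@annotation))
    cat("  annotation:", sum(!is.na(object@annotation$source_species)),
        "orthogroups annotated\n")
})

#' Parse an orthogroup assignment table
#'
#' The table has one row per orthogroup: an orthogroup ID column followed
#' by one column per species holding comma-separated member transcript
#' IDs (empty cell = zero members; the row is retained).
#'
#' @param path TSV file; header row names the species columns.
#' @return an \linkS4class{OrthogroupMap}.
#' @export
parseOrthogroupTable <- function(path) {
  tab <- read_tsv(path, colClasses = "character")
  if (ncol(tab) < 2L) stop("format error: need an ID column plus species")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("format error: duplicate orthogroup ID ",
         ids[duplicated(ids)][1])
  species <- names(tab)[-1]
  membership <- lapply(seq_along(ids), function(i) {
    m <- lapply(species, function(s) {
      cell <- tab[i, s]
      if (is.na(cell) || cell == "") character() else
        unique(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    names(m) <- species
    m
  })
  names(membership) <- ids
  mem_flat <- lapply(membership, unlist, use.names = FALSE)
  all_members <- unlist(mem_flat, use.names = FALSE)
  og_of <- rep(ids, lengths(mem_flat))
  for (t in unique(all_members[duplicated(all_members)]))
    if (length(unique(og_of[all_members == t])) > 1L)
      stop("format error: transcript '", t,
           "' assigned to more than one orthogroup")
  new("OrthogroupMap", membership = membership, species = species,
      annotation = S4Vectors::DataFrame(row.names = ids))
}

## Flatten an OrthogroupMap back to its table form (used by writers).
orthogroupTableFrame <- function(map) {
  df <- data.frame(og_id = ogIds(map), stringsAsFactors = FALSE)
  for (s in map@species)
    df[[s]] <- vapply(map@membership, function(m)
      paste(m[[s]], collapse = ","), character(1))
  df
}

#' Transfer annotation to orthogroups by reference priority
#'
#' Each orthogroup is annotated from the highest-priority reference
#' species that contributes at least one member; within that species the
#' member with the lexicographically smallest ID supplies the annotation.
#' Orthogroups with no reference member stay unannotated (a valid state).
#'
#' @param map an \linkS4class{OrthogroupMap}.
#' @param ref_annotations named list (species -> data.frame with columns
#'   \code{transcript}, \code{description}, \code{go} (comma-separated),
#'   \code{tf}).
#' @param priority ordered character vector of reference species.
#' @return the map with its \code{annotation} slot filled
#'   (\code{source_species}, \code{description}, \code{go} list column,
#'   \code{tf}).
#' @export
transferAnnotation <- function(map, ref_annotations, priority) {
  if (!length(priority)) stop("priority list must be non-empty")
  ids <- ogIds(map)
  src <- rep(NA_character_, length(ids))
  desc <- rep(NA_character_, length(ids))
  golist <- vector("list", length(ids))
  tf <- rep(NA, length(ids))
  lookup <- lapply(ref_annotations, function(a) {
    rownames(a) <- a$transcript
    a
  })
  for (i in seq_along(ids)) {
    for (s in priority) {
      mem <- sort(ogMembers(map, ids[i], s))
      mem <- mem[mem %in% rownames(lookup[[s]] %||% data.frame())]
      if (length(mem)) {
        a <- lookup[[s]][mem[1], ]
        src[i] <- s
        desc[i] <- a$description
        golist[[i]] <- if (is.na(a$go) || a$go == "") character() else
          strsplit(a$go, ",", fixed = TRUE)[[1]]
        tf[i] <- isTRUE(a$tf) || identical(a$tf, "TRUE")
        break
      }
    }
    if (is.null(golist[[i]])) golist[[i]] <- character()
  }
  map@annotation <- S4Vectors::DataFrame(
    source_species = src, description = desc,
    go = I(golist), tf = tf, row.names = ids)
  map
}

#' Orthogroups shared by all listed species
#'
#' @param map an \linkS4class{OrthogroupMap}.
#' @param species species that must each contribute at least one member.
#' @param keep_features optional transcript whitelist (e.g. the curated,
#'   expression-filtered sets); members outside it do not count.
#' @return sorted character vector of orthogroup IDs.
#' @export
sharedOrthogroups <- function(map, species, keep_features = NULL) {
  unknown <- setdiff(species, map@species)
  if (length(unknown))
    stop("input error: unknown species ", paste(unknown, collapse = ", "))
  ok <- vapply(map@membership, function(m) {
    all(vapply(species, function(s) {
      mem <- m[[s]]
      if (!is.null(keep_features)) mem <- intersect(mem, keep_features)
      length(mem) > 0L
    }, logical(1)))
  }, logical(1))
  sort(names(map@membership)[ok])
}

#' Aggregate transcript expression to orthogroup level
#'
#' Orthogroup value = sum of its member transcripts' values per sample
#' (exact for counts; single-copy orthogroups pass through unchanged).
#' Per-species count matrices are combined into one orthogroup x library
#' matrix; a library of species s only receives members of species s.
#'
#' @param counts named list (species -> transcript x sample matrix) or a
#'   single matrix when only one species is aggregated.
#' @param map an \linkS4class{OrthogroupMap}.
#' @param species species to include (default: names of \code{counts}).
#' @param samples named list of per-species sample data.frames with
#'   columns \code{sample}, \code{species}, \code{segment},
#'   \code{replicate}; defaults parse the matrix column names
#'   (\code{species_segment_rep}).
#' @param og_ids orthogroups to aggregate (default all in the map).
#' @param strict error on members missing from \code{counts} (default);
#'   permissive mode treats them as zero.
#' @param lib_sizes named list of per-species library-size vectors; the
#'   default uses the column sums of the supplied matrices.
#' @return an \linkS4class{OGExpression}.
#' @export
aggregateExpression <- function(counts, map, species = NULL,
                                samples = NULL, og_ids = NULL,
                                strict = TRUE, lib_sizes = NULL) {
  if (is.matrix(counts)) counts <- list(counts)
  if (is.null(species)) species <- names(counts)
  if (is.null(species) || any(!nzchar(species)))
    stop("species labels are required")
  names(counts) <- species
  if (is.null(og_ids)) og_ids <- ogIds(map)
  mats <- list(); cds <- list(); prov <- stats::setNames(
    vector("list", length(og_ids)), og_ids)
  for (s in species) {
    cm <- as.matrix(counts[[s]])
    agg <- matrix(0, length(og_ids), ncol(cm),
                  dimnames = list(og_ids, colnames(cm)))
    for (og in og_ids) {
      mem <- ogMembers(map, og, s)
      missing <- setdiff(mem, rownames(cm))
      if (length(missing) && strict)
        stop("input error: member transcript(s) missing from counts for ",
             og, " (", s, "): ", paste(utils::head(missing, 3),
                                       collapse = ", "))
      mem <- setdiff(mem, missing)
      if (length(mem))
        agg[og, ] <- colSums(cm[mem, , drop = FALSE])
      prov[[og]] <- c(prov[[og]], mem)
    }
    mats[[s]] <- agg
    if (!is.null(samples)) {
      cd <- samples[[s]]
    } else {
      parts <- strsplit(colnames(cm), "_")
      cd <- data.frame(sample = colnames(cm),
                       species = s,
                       segment = vapply(parts, `[`, "", 2),
                       replicate = as.integer(sub("^r", "",
                         vapply(parts, `[`, "", 3))),
                       stringsAsFactors = FALSE)
    }
    cd$lib_size <- if (!is.null(lib_sizes)) unname(lib_sizes[[s]][cd$sample])
                   else colSums(cm)
    cds[[s]] <- cd
  }
  mat <- do.call(cbind, mats)
  cd <- do.call(rbind, cds)
  rownames(cd) <- cd$sample
  colnames(mat) <- cd$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(cd[, c("species", "segment",
                                          "replicate", "lib_size")]))
  out <- new("OGExpression", se)
  S4Vectors::metadata(out)$provenance <- prov
  out
}

#' @describeIn OGExpression-helpers subset an OGExpression to one species
#'   (keeps provenance).
#' @param x an \linkS4class{OGExpression}.
#' @param species species label.
#' @name OGExpression-helpers
#' @export
ogSubsetSpecies <- function(x, species) {
  x[, colData(x)$species %in% species]
}
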