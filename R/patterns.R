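## Segment-profile analytics: z-score profiles, cross-species pattern
## conservation, pathway-level DEO percentages, relative-expression
## heatmap matrices, and sink/source zone classification.

#' Z-score a segment profile
#'
#' @param segment_means numeric vector of per-segment mean expression
#'   (at least 2 segments).
#' @return \code{(x - mean) / sd} with sample sd (n - 1); a constant
#'   profile maps to the zero vector.
#' @export
zscoreProfile <- function(segment_means) {
  if (length(segment_means) < 2L)
    stop("input error: need at least 2 segments")
  s <- stats::sd(segment_means)
  if (!is.finite(s) || s == 0) return(rep(0, length(segment_means)))
  (segment_means - mean(segment_means)) / s
}

#' Per-segment mean cpm profiles
#'
#' TMM-normalized cpm averaged over replicates, per species and segment,
#' for the requested orthogroups. This is the profile definition used by
#' the conservation calls and the heatmaps.
#'
#' @param og_expr an \linkS4class{OGExpression}.
#' @param og_ids rows to profile (default all).
#' @param segments ordered segment labels (default: order of appearance).
#' @param normalize compute TMM within each species (default TRUE).
#' @return named list (species -> og x segment matrix of mean cpm).
#' @export
segmentProfiles <- function(og_expr, og_ids = rownames(og_expr),
                            segments = NULL, normalize = TRUE) {
  cd <- colData(og_expr)
  if (is.null(segments)) segments <- unique(cd$segment)
  out <- list()
  for (s in unique(cd$species)) {
    sel <- cd$species == s
    counts <- assay(og_expr)[, sel, drop = FALSE]
    ls <- cd$lib_size[sel]
    if (normalize) {
      nf <- tmmFactors(counts, lib_sizes = ls)
      ls <- nf$effective_lib_sizes
    }
    cpms <- cpm(counts, ls)
    seg <- cd$segment[sel]
    prof <- vapply(segments, function(g)
      rowMeans(cpms[, seg == g, drop = FALSE]), numeric(nrow(cpms)))
    out[[s]] <- prof[og_ids, , drop = FALSE]
  }
  out
}

#' Cross-species expression-pattern conservation
#'
#' A species pair is conserved for an orthogroup iff the Pearson
#' correlation of the two z-scored segment profiles reaches
#' \code{r_threshold}; a constant profile (zero z-vector) is never
#' conserved. The overall call is conserved iff every pair involving the
#' focal species is conserved (set \code{all_pairs = FALSE} to require
#' only one such pair).
#'
#' @param z_profiles named list (species -> z vector over the same
#'   ordered segments) for one orthogroup.
#' @param r_threshold Pearson threshold (default 0.8).
#' @param focal_species species anchoring the overall call (default the
#'   last listed species).
#' @param all_pairs require all focal pairs conserved (default TRUE).
#' @return list with \code{pairs} (data.frame species_a, species_b, r,
#'   conserved) and \code{conserved} (overall logical).
#' @export
patternConservation <- function(z_profiles, r_threshold = 0.8,
                                focal_species = NULL, all_pairs = TRUE) {
  sp <- names(z_profiles)
  len <- lengths(z_profiles)
  if (length(unique(len)) != 1L)
    stop("input error: profiles cover different segment sets")
  if (is.null(focal_species)) focal_species <- sp[length(sp)]
  cmb <- utils::combn(sp, 2)
  pairs <- data.frame(species_a = cmb[1, ], species_b = cmb[2, ],
                      r = NA_real_, conserved = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    za <- z_profiles[[pairs$species_a[i]]]
    zb <- z_profiles[[pairs$species_b[i]]]
    if (all(za == 0) || all(zb == 0)) {
      pairs$r[i] <- NA_real_    # constant vs anything: not conserved
    } else {
      pairs$r[i] <- stats::cor(za, zb)
      pairs$conserved[i] <- pairs$r[i] >= r_threshold
    }
  }
  foc <- pairs$species_a == focal_species | pairs$species_b == focal_species
  overall <- if (all_pairs) all(pairs$conserved[foc])
             else any(pairs$conserved[foc])
  list(pairs = pairs, conserved = overall)
}

#' Conservation calls for many orthogroups
#'
#' @param profiles output of \code{\link{segmentProfiles}}.
#' @param og_ids orthogroups to call (default rows of the first species).
#' @inheritParams patternConservation
#' @return data.frame (og, conserved, plus one r column per species pair).
#' @export
conservationCalls <- function(profiles, og_ids = NULL, r_threshold = 0.8,
                              focal_species = NULL, all_pairs = TRUE) {
  if (is.null(og_ids)) og_ids <- rownames(profiles[[1]])
  rows <- lapply(og_ids, function(og) {
    z <- lapply(profiles, function(m) zscoreProfile(m[og, ]))
    pc <- patternConservation(z, r_threshold, focal_species, all_pairs)
    r <- stats::setNames(pc$pairs$r, paste0("r_", pc$pairs$species_a, "_",
                                            pc$pairs$species_b))
    c(list(og = og, conserved = pc$conserved), as.list(r))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Pathway-level DEO percentages
#'
#' For one species pair at one segment, counts the pathway orthogroups
#' significantly up in either species and expresses them as percentages
#' of the pathway size (one decimal, rounded half-to-even). Pathway
#' members absent from the tested set are dropped with a warning.
#'
#' @param deo_results DE table from \code{\link{deoBetweenSpecies}}
#'   (direction up_in_A / up_in_B refers to the species pair order).
#' @param pathway_lists named list (pathway -> orthogroup IDs).
#' @param species_pair,segment labels recorded in the output.
#' @return data.frame with one row per pathway: \code{n_pathway_og},
#'   \code{n_up_in_A}, \code{n_up_in_B}, \code{pct_up_in_A},
#'   \code{pct_up_in_B}.
#' @export
pathwayDEOPercentages <- function(deo_results, pathway_lists,
                                  species_pair = c("A", "B"),
                                  segment = NA_character_) {
  tested <- deo_results$feature_id
  rows <- lapply(names(pathway_lists), function(p) {
    og <- pathway_lists[[p]]
    out <- setdiff(og, tested)
    if (length(out)) {
      warning("pathway '", p, "': ", length(out),
              " orthogroup(s) not in the tested set were excluded")
      og <- intersect(og, tested)
    }
    sub <- deo_results[deo_results$feature_id %in% og, ]
    nA <- sum(sub$direction == "up_in_A")
    nB <- sum(sub$direction == "up_in_B")
    data.frame(pathway = p,
               species_pair = paste(species_pair, collapse = "-"),
               segment = segment, n_pathway_og = length(og),
               n_up_in_A = nA, n_up_in_B = nB,
               pct_up_in_A = pct1(nA, length(og)),
               pct_up_in_B = pct1(nB, length(og)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative-expression heatmap matrix
#'
#' Row-scales each orthogroup's mean expression to [0, 1] (min-max) across
#' all species x segment cells; constant rows map to 0.5.
#'
#' @param profiles output of \code{\link{segmentProfiles}} (species ->
#'   og x segment mean matrix).
#' @param og_list orthogroups to include (must exist in the profiles).
#' @return matrix og x (species_segment), values in [0, 1].
#' @export
heatmapMatrix <- function(profiles, og_list) {
  if (!length(og_list)) stop("input error: empty orthogroup list")
  miss <- setdiff(og_list, rownames(profiles[[1]]))
  if (length(miss))
    stop("input error: orthogroup(s) absent from profiles: ",
         paste(utils::head(miss, 3), collapse = ", "))
  wide <- do.call(cbind, lapply(names(profiles), function(s) {
    m <- profiles[[s]][og_list, , drop = FALSE]
    cn <- colnames(m) %||% paste0("seg", seq_len(ncol(m)))
    colnames(m) <- paste(s, cn, sep = "_")
    m
  }))
  t(apply(wide, 1, function(x) {
    r <- range(x)
    if (r[1] == r[2]) rep(0.5, length(x)) else (x - r[1]) / (r[2] - r[1])
  }))
}

#' Classify leaf segments as sink or source
#'
#' Z-scores each marker's segment profile and labels a segment "sink" iff
#' the mean z of sink markers exceeds the mean z of source markers there.
#'
#' @param marker_profiles named list or matrix (marker -> segment means).
#' @param marker_roles named character vector, marker -> "sink"/"source".
#' @return named character vector, segment -> "sink"/"source".
#' @export
classifySinkSource <- function(marker_profiles, marker_roles) {
  if (is.matrix(marker_profiles))
    marker_profiles <- stats::setNames(
      lapply(seq_len(nrow(marker_profiles)),
             function(i) marker_profiles[i, ]),
      rownames(marker_profiles))
  if (!all(c("sink", "source") %in% marker_roles))
    stop("input error: need at least one marker of each role")
  z <- lapply(marker_profiles, zscoreProfile)
  zs <- do.call(rbind, z)
  sink_mean <- colMeans(zs[names(marker_roles)[marker_roles == "sink"], ,
                           drop = FALSE])
  source_mean <- colMeans(zs[names(marker_roles)[marker_roles == "source"], ,
                             drop = FALSE])
  lab <- ifelse(sink_mean > source_mean, "sink", "source")
  stats::setNames(lab, colnames(zs) %||% names(marker_profiles[[1]]))
}
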