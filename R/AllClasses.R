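#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic leaf-gradient dataset generator. The defaults
#' emulate the study design the pipeline targets: three species (a C3, a
#' Proto-Kranz and a C4 grass), four leaf segments sampled along the
#' developmental gradient (S1 base to S7 tip), and three pooled biological
#' replicates per species x segment.
#'
#' @slot seed integer; master seed, split internally into per-stage streams.
#' @slot n_og number of orthogroups to simulate.
#' @slot species character vector of species labels.
#' @slot segments ordered character vector of leaf segment labels.
#' @slot n_reps replicates per species x segment.
#' @slot copy_number_probs probabilities of 0..3 gene copies per species
#'   (applied per orthogroup and species; named "0".."3").
#' @slot frac_species_absent fraction of orthogroups forced absent in at
#'   least one species.
#' @slot baseline_logmean_range log2 range of baseline expression weights.
#' @slot dispersion_range range of the negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @slot profile_weights mixing weights over the developmental profile
#'   classes ascending, descending, peaked, flat.
#' @slot profile_amplitude_range log2 amplitude range of non-flat profiles.
#' @slot frac_pattern_divergent fraction of orthogroups whose profile class
#'   is drawn independently per species (the rest share one class).
#' @slot planted_deo data.frame with columns pathway, species, segment,
#'   log2fc: cross-species effects added to the stated cells.
#' @slot frac_junk fraction of extra junk transcripts (expected cpm < 1).
#' @slot frac_noncoding fraction of extra transcripts whose best ORF is
#'   shorter than \code{orf_min_len}.
#' @slot isoform_rate mean number of extra isoforms per gene (Poisson).
#' @slot library_size_range range of per-library sequencing depths; sizes
#'   are drawn log-uniformly so normalization has work to do.
#' @slot junk_cpm_range target expected-cpm range for junk transcripts.
#' @slot tf_frac fraction of orthogroups flagged as transcription factors.
#' @slot orf_min_len minimum ORF length (nt) used when labelling
#'   transcripts as coding.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  n_og = "integer",
  species = "character",
  segments = "character",
  n_reps = "integer",
  copy_number_probs = "numeric",
  frac_species_absent = "numeric",
  baseline_logmean_range = "numeric",
  dispersion_range = "numeric",
  profile_weights = "numeric",
  profile_amplitude_range = "numeric",
  frac_pattern_divergent = "numeric",
  planted_deo = "data.frame",
  frac_junk = "numeric",
  frac_noncoding = "numeric",
  isoform_rate = "numeric",
  library_size_range = "numeric",
  junk_cpm_range = "numeric",
  tf_frac = "numeric",
  orf_min_len = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  frac_fields <- c("frac_species_absent", "frac_pattern_divergent",
                   "frac_junk", "frac_noncoding", "tf_frac")
  for (f in frac_fields) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a single value in [0, 1]", f))
  }
  if (object@n_og < 1L) msg <- c(msg, "'n_og' must be >= 1")
  if (object@n_reps < 2L) msg <- c(msg, "'n_reps' must be >= 2")
  if (length(object@species) < 2L)
    msg <- c(msg, "'species' needs at least two labels")
  if (length(object@segments) < 2L)
    msg <- c(msg, "'segments' needs at least two labels")
  w <- object@profile_weights
  if (length(w) != 4L || is.null(names(w)) ||
      !setequal(names(w), c("ascending", "descending", "peaked", "flat")))
    msg <- c(msg, "'profile_weights' must be named ascending/descending/peaked/flat")
  else if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msg <- c(msg, "'profile_weights' must be non-negative and sum to 1")
  p <- object@copy_number_probs
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "'copy_number_probs' must be 4 non-negative values summing to 1")
  if (p[1] > 1 - 1e-8)
    msg <- c(msg, "'copy_number_probs' leaves no species with any copy")
  for (f in c("baseline_logmean_range", "dispersion_range",
              "profile_amplitude_range", "library_size_range",
              "junk_cpm_range")) {
    v <- slot(object, f)
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2])
      msg <- c(msg, sprintf("'%s' must be an ordered (lo, hi) pair", f))
  }
  if (any(object@dispersion_range < 0))
    msg <- c(msg, "'dispersion_range' must be non-negative")
  if (any(object@library_size_range <= 0))
    msg <- c(msg, "'library_size_range' must be positive")
  if (any(object@junk_cpm_range <= 0) || object@junk_cpm_range[2] >= 1)
    msg <- c(msg, "'junk_cpm_range' must lie in (0, 1) so junk stays below 1 cpm")
  pd <- object@planted_deo
  if (nrow(pd) &&
      !all(c("pathway", "species", "segment", "log2fc") %in% names(pd)))
    msg <- c(msg, "'planted_deo' needs columns pathway, species, segment, log2fc")
  if (nrow(pd) && !all(pd$species %in% object@species))
    msg <- c(msg, "'planted_deo' references unknown species")
  if (nrow(pd) && !all(pd$segment %in% object@segments))
    msg <- c(msg, "'planted_deo' references unknown segments")
  if (length(msg)) msg else TRUE
})

#' Orthogroup membership map
#'
#' Maps each orthogroup to its member transcripts per species, together with
#' transferred functional annotation (description, GO terms, transcription
#' factor flag) and per-species copy numbers. An orthogroup row exists even
#' when a species contributes zero members.
#'
#' @slot membership named list: og_id -> named list (species -> character
#'   vector of member transcript IDs).
#' @slot species character; all species columns of the source table.
#' @slot annotation \code{DataFrame} indexed by og_id with columns
#'   \code{source_species}, \code{description}, \code{go} (CharacterList-like
#'   list column), \code{tf}.
#' @export
setClass("OrthogroupMap", representation(
  membership = "list",
  species = "character",
  annotation = "DataFrame"
))

setValidity("OrthogroupMap", function(object) {
  msg <- character()
  if (is.null(names(object@membership)) ||
      anyDuplicated(names(object@membership)))
    msg <- c(msg, "membership must be uniquely named by orthogroup ID")
  bad <- vapply(object@membership, function(m)
    !setequal(names(m), object@species), logical(1))
  if (any(bad))
    msg <- c(msg, "every orthogroup must carry one entry per species")
  if (nrow(object@annotation) &&
      !identical(rownames(object@annotation), names(object@membership)))
    msg <- c(msg, "annotation rows must align with membership")
  if (length(msg)) msg else TRUE
})

#' Orthogroup-level expression container
#'
#' A \code{SummarizedExperiment} whose rows are orthogroups and whose columns
#' are libraries (named \code{species_segment_rep}); \code{colData} carries
#' \code{species}, \code{segment}, \code{replicate}, and \code{lib_size}.
#' Each orthogroup x sample value is the sum of the member transcripts'
#' values in that sample (exact for counts). Provenance (the member
#' transcripts summed per orthogroup) lives in \code{metadata()$provenance}.
#'
#' @export
setClass("OGExpression", contains = "SummarizedExperiment")

setValidity("OGExpression", function(object) {
  cd <- colData(object)
  need <- c("species", "segment", "replicate", "lib_size")
  if (!all(need %in% names(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  if (any(cd$lib_size <= 0)) return("lib_size must be positive")
  TRUE
})

#' Gene Ontology DAG with annotation closure
#'
#' Holds the term hierarchy (child -> parents; acyclic, multiple parents
#' allowed) and, for each term, the features annotated to it after
#' true-path-rule closure (a feature annotated to a term is annotated to all
#' of the term's ancestors).
#'
#' @slot parents named list: term -> character vector of parent terms.
#' @slot annotated named list: term -> character vector of features
#'   (closure already applied).
#' @slot depth named integer: longest-path distance of each term from a
#'   root; used to schedule the bottom-up elim traversal.
#' @export
setClass("GODag", representation(
  parents = "list",
  annotated = "list",
  depth = "integer"
))
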