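## Orchestration: configuration, dataset I/O, and the end-to-end run
## (curation -> aggregation -> differential expression -> patterns ->
## enrichment), with every result table written as TSV.

#' Pipeline run configuration
#'
#' Bundles the analysis thresholds, the focal species, the annotation
#' priority order, and the seed recorded in the run manifest. Thresholds
#' default to the study's reported cutoffs (FDR < 0.01, |log2FC| > 1,
#' expression filter at 1 cpm in 3 libraries, 95 percent redundancy
#' identity, 100 nt minimum ORF).
#'
#' @param alpha FDR threshold for significance.
#' @param fc_threshold |log2 fold change| must strictly exceed this.
#' @param min_cpm,min_libraries expression-filter thresholds.
#' @param identity_threshold redundancy-collapse identity.
#' @param orf_min_len minimum ORF length (nt).
#' @param r_conserved Pearson threshold for pattern conservation.
#' @param loading_fraction PCA loading tail fraction.
#' @param focal_species species anchoring conservation calls (default the
#'   C4 species when present, else the last species).
#' @param priority annotation-transfer priority order over reference
#'   species.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return a validated list of class \code{RunConfig}.
#' @export
runConfig <- function(alpha = 0.01, fc_threshold = 1, min_cpm = 1,
                      min_libraries = 3L, identity_threshold = 0.95,
                      orf_min_len = 100L, r_conserved = 0.8,
                      loading_fraction = 0.05, focal_species = NULL,
                      priority = c("REFA", "REFB"), seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, fc_threshold >= 0, min_cpm >= 0,
            min_libraries >= 1, identity_threshold > 0,
            identity_threshold <= 1, orf_min_len >= 3,
            r_conserved >= -1, r_conserved <= 1,
            loading_fraction > 0, loading_fraction < 0.5)
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 min_cpm = min_cpm, min_libraries = as.integer(min_libraries),
                 identity_threshold = identity_threshold,
                 orf_min_len = as.integer(orf_min_len),
                 r_conserved = r_conserved,
                 loading_fraction = loading_fraction,
                 focal_species = focal_species, priority = priority,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a dataset directory
#'
#' Loads the plain-text layout written by \code{\link{writeSyntheticData}}
#' (or assembled by hand to the same convention) back into the structure
#' \code{\link{runPipeline}} consumes.
#'
#' @param dir directory with per-species \code{<sp>_transcripts.fasta},
#'   \code{<sp>_counts.tsv}, \code{<sp>_tpm.tsv}, plus
#'   \code{orthogroups.tsv}, \code{go_edges.tsv}, \code{go_annotation.tsv}
#'   and \code{pathways.tsv}.
#' @param species focal species labels (default: inferred from the FASTA
#'   file names).
#' @return list with the same data elements as
#'   \code{\link{simulateDataset}} output (no truth tables).
#' @export
readDatasetDir <- function(dir, species = NULL) {
  fa <- list.files(dir, pattern = "_transcripts\\.fasta$")
  if (is.null(species)) species <- sub("_transcripts\\.fasta$", "", fa)
  transcripts <- list(); counts <- list(); tpm <- list()
  for (s in species) {
    transcripts[[s]] <- Biostrings::readDNAStringSet(
      file.path(dir, paste0(s, "_transcripts.fasta")))
    cm <- read_tsv(file.path(dir, paste0(s, "_counts.tsv")))
    counts[[s]] <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts[[s]]) <- cm[[1]]
    tm <- read_tsv(file.path(dir, paste0(s, "_tpm.tsv")))
    tpm[[s]] <- as.matrix(tm[, -1, drop = FALSE])
    rownames(tpm[[s]]) <- tm[[1]]
    ## derive gene_id grouping from the <gene>_t<k> naming convention
    S4Vectors::mcols(transcripts[[s]]) <- S4Vectors::DataFrame(
      gene_id = sub("_t[0-9]+$", "", names(transcripts[[s]])))
  }
  ogmap <- parseOrthogroupTable(file.path(dir, "orthogroups.tsv"))
  go_ann_path <- file.path(dir, "go_annotation.tsv")
  pathways <- read_tsv(file.path(dir, "pathways.tsv"))
  list(transcripts = transcripts, counts = counts, tpm = tpm,
       ogmap = ogmap,
       go_edges = read_tsv(file.path(dir, "go_edges.tsv")),
       go_annotation = if (file.exists(go_ann_path)) read_tsv(go_ann_path),
       pathways = pathways, species = species)
}

## consecutive segment pairs of an ordered segment vector
segment_transitions <- function(segments)
  lapply(seq_len(length(segments) - 1L),
         function(i) segments[c(i, i + 1L)])

#' Run the full comparative pipeline
#'
#' Executes curation, orthogroup aggregation, annotation transfer,
#' within-species DEG and cross-species DEO testing, pathway DEO
#' profiling, pattern-conservation calls, heatmap matrices, sink/source
#' classification, GO enrichment (elim) of the DEO sets, and PCA with
#' loading-set enrichment, writing each result table as TSV under
#' \code{outdir}. The run is deterministic: identical inputs and config
#' produce byte-identical output files.
#'
#' @param data a dataset as returned by \code{\link{simulateDataset}} or
#'   \code{\link{readDatasetDir}}.
#' @param config a \code{\link{runConfig}}.
#' @param outdir output directory (created; existing tables overwritten).
#' @param ref_annotations optional named list of reference annotation
#'   tables (defaults to \code{data$ref_annotations}).
#' @return invisibly, the result bundle: a list with elements
#'   \code{curation}, \code{og_expr}, \code{shared_og}, \code{ogmap},
#'   \code{deg}, \code{deo}, \code{pathway_deo}, \code{conservation},
#'   \code{heatmaps}, \code{sink_source}, \code{enrichment}, \code{pca},
#'   and \code{manifest}.
#' @export
runPipeline <- function(data, config = runConfig(), outdir,
                        ref_annotations = data$ref_annotations) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  species <- names(data$counts)
  segments <- unique(sub("^[^_]+_([^_]+)_.*$", "\\1",
                         colnames(data$counts[[1]])))
  focal <- config$focal_species %||%
    (if ("C4" %in% species) "C4" else species[length(species)])
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ## -- stage 1: curation -----------------------------------------------
  curation <- list()
  for (s in species) {
    cur <- curateTranscripts(
      data$transcripts[[s]], data$counts[[s]], data$tpm[[s]],
      min_cpm = config$min_cpm, min_libraries = config$min_libraries,
      identity_threshold = config$identity_threshold,
      orf_min_len = config$orf_min_len)
    curation[[s]] <- cur
    note("curation [", s, "]: ",
         paste(sprintf("%s=%d", cur$report$stage, cur$report$n),
               collapse = " "))
    rep_df <- cur$report
    rep_df$species <- s
    write_tsv(rep_df[, c("species", "stage", "n")],
              file.path(outdir, paste0("curation_", s, ".tsv")))
  }
  kept <- unlist(lapply(curation, `[[`, "kept"), use.names = FALSE)

  ## -- stage 2: aggregation and annotation -----------------------------
  og_expr <- aggregateExpression(data$counts, data$ogmap, species = species)
  shared_og <- sharedOrthogroups(data$ogmap, species, keep_features = kept)
  note("aggregation: ", nrow(og_expr), " orthogroups, ",
       length(shared_og), " shared by all species")
  ogmap <- data$ogmap
  if (!is.null(ref_annotations))
    ogmap <- transferAnnotation(ogmap, ref_annotations, config$priority)
  ann <- ogAnnotation(ogmap)
  tf_flags <- if (ncol(ann)) stats::setNames(!is.na(ann$tf) & ann$tf,
                                             rownames(ann))
              else stats::setNames(rep(FALSE, nrow(og_expr)),
                                   rownames(og_expr))
  write_matrix_tsv(assay(og_expr), file.path(outdir, "og_counts.tsv"),
                   id_col = "og_id")
  write_tsv(data.frame(og = shared_og), file.path(outdir, "shared_og.tsv"))

  ## -- stage 3: differential expression --------------------------------
  deg <- list(); deg_counts <- list()
  for (s in species) {
    sub <- ogSubsetSpecies(og_expr, s)
    for (tp in segment_transitions(segments)) {
      key <- paste0(s, ":", tp[1], "-", tp[2])
      tab <- degBetweenSegments(sub, tp, alpha = config$alpha,
                                fc_threshold = config$fc_threshold)
      deg[[key]] <- tab
      deg_counts[[key]] <- sum(tab$significant)
      write_tsv(tab, file.path(outdir, paste0(
        "deg_", s, "_", tp[1], "_", tp[2], ".tsv")))
    }
    note("DEG [", s, "]: ",
         paste(vapply(segment_transitions(segments), function(tp)
           sprintf("%s-%s=%d", tp[1], tp[2],
                   deg_counts[[paste0(s, ":", tp[1], "-", tp[2])]]),
           character(1)), collapse = " "))
  }
  pairs <- utils::combn(species, 2, simplify = FALSE)
  deo <- list()
  for (pr in pairs) for (g in segments) {
    key <- paste0(pr[1], "-", pr[2], ":", g)
    deo[[key]] <- deoBetweenSpecies(og_expr, pr, g, og_ids = shared_og,
                                    alpha = config$alpha,
                                    fc_threshold = config$fc_threshold,
                                    tf_flags = tf_flags)
    write_tsv(deo[[key]]$results, file.path(outdir, paste0(
      "deo_", pr[1], "_", pr[2], "_", g, ".tsv")))
  }
  note("DEO: ", paste(vapply(names(deo), function(k)
    sprintf("%s=%d", k, sum(deo[[k]]$results$significant)), character(1)),
    collapse = " "))

  ## -- stage 4: patterns -----------------------------------------------
  pw <- split(data$pathways$og, data$pathways$pathway)
  pw <- lapply(pw, intersect, shared_og)
  profiles <- segmentProfiles(og_expr, og_ids = shared_og,
                              segments = segments)
  conservation <- conservationCalls(profiles, r_threshold = config$r_conserved,
                                    focal_species = focal)
  write_tsv(conservation, file.path(outdir, "conservation.tsv"))
  pathway_deo <- do.call(rbind, lapply(names(deo), function(k) {
    pr <- strsplit(sub(":.*", "", k), "-")[[1]]
    g <- sub(".*:", "", k)
    pathwayDEOPercentages(deo[[k]]$results,
                          pw[!names(pw) %in% c("sink_markers",
                                               "source_markers")],
                          species_pair = pr, segment = g)
  }))
  write_tsv(pathway_deo, file.path(outdir, "pathway_deo.tsv"))
  heatmaps <- lapply(pw[lengths(pw) > 0], function(og)
    heatmapMatrix(profiles, og))
  for (p in names(heatmaps))
    write_matrix_tsv(round(heatmaps[[p]], 6),
                     file.path(outdir, paste0("heatmap_", p, ".tsv")),
                     id_col = "og_id")
  sink_source <- NULL
  if (all(c("sink_markers", "source_markers") %in% names(pw)) &&
      length(pw$sink_markers) && length(pw$source_markers)) {
    sink_source <- do.call(rbind, lapply(species, function(s) {
      mk <- c(pw$sink_markers, pw$source_markers)
      roles <- stats::setNames(rep(c("sink", "source"),
                                   c(length(pw$sink_markers),
                                     length(pw$source_markers))), mk)
      lab <- classifySinkSource(profiles[[s]][mk, , drop = FALSE], roles)
      data.frame(species = s, segment = names(lab), zone = unname(lab),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(sink_source, file.path(outdir, "sink_source.tsv"))
  }

  ## -- stage 5: enrichment and PCA -------------------------------------
  enrichment <- NULL; pca <- NULL
  if (!is.null(data$go_edges)) {
    og_go <- og_level_go(ogmap, data$go_annotation)
    dag <- goDag(data$go_edges, og_go)
    universe <- intersect(shared_og, unique(og_go$feature))
    enr_rows <- list()
    for (k in names(deo)) {
      study <- intersect(deo[[k]]$results$feature_id[
        deo[[k]]$results$significant], universe)
      if (length(study) < 2L) next
      p_elim <- elimGO(dag, study, universe, alpha = config$alpha)
      enr_rows[[k]] <- data.frame(contrast = k, term = names(p_elim),
                                  p_elim = unname(p_elim),
                                  significant = p_elim < config$alpha,
                                  stringsAsFactors = FALSE)
    }
    enrichment <- do.call(rbind, enr_rows)
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(outdir, "go_enrichment.tsv"))
    ## PCA of samples on log2(cpm + 1) over shared orthogroups
    lcpm <- log2(cpm(assay(og_expr)[shared_og, , drop = FALSE],
                     colData(og_expr)$lib_size) + 1)
    pca_res <- pcaLoadings(lcpm, n_components = min(4L, min(dim(lcpm))))
    pca_enr <- list()
    for (pc in colnames(pca_res$loadings)[1:min(2, ncol(pca_res$loadings))]) {
      sets <- topLoadingSets(pca_res$loadings[, pc],
                             fraction = config$loading_fraction)
      for (side in c("top", "bottom")) {
        study <- intersect(sets[[side]], universe)
        if (length(study) < 2L) next
        p_elim <- elimGO(dag, study, universe, alpha = config$alpha)
        pca_enr[[paste(pc, side)]] <- data.frame(
          component = pc, side = side, term = names(p_elim),
          p_elim = unname(p_elim), significant = p_elim < config$alpha,
          stringsAsFactors = FALSE)
      }
    }
    pca <- list(result = pca_res,
                enrichment = do.call(rbind, pca_enr))
    write_matrix_tsv(round(pca_res$scores, 6),
                     file.path(outdir, "pca_scores.tsv"), id_col = "sample")
    write_tsv(data.frame(component = colnames(pca_res$loadings),
                         variance_explained =
                           round(pca_res$variance_explained, 6)),
              file.path(outdir, "pca_variance.tsv"))
    if (!is.null(pca$enrichment))
      write_tsv(pca$enrichment, file.path(outdir, "pca_enrichment.tsv"))
  }

  ## -- manifest ---------------------------------------------------------
  cfg_flat <- unlist(config[!vapply(config, is.null, logical(1))])
  manifest <- data.frame(
    key = c(names(cfg_flat), "focal_species", "package_version"),
    value = c(unname(as.character(cfg_flat)), focal,
              as.character(utils::packageVersion("OrthoDEO"))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))

  invisible(list(curation = curation, og_expr = og_expr,
                 shared_og = shared_og, ogmap = ogmap, deg = deg,
                 deo = deo, pathway_deo = pathway_deo,
                 conservation = conservation, heatmaps = heatmaps,
                 sink_source = sink_source, enrichment = enrichment,
                 pca = pca, manifest = manifest))
}

## Orthogroup-level GO annotation: prefer the transferred annotation on
## the map; fall back to mapping a transcript-level (feature, go) table
## through orthogroup membership.
og_level_go <- function(ogmap, go_annotation) {
  ann <- ogAnnotation(ogmap)
  if (ncol(ann) && any(lengths(ann$go) > 0)) {
    ids <- rownames(ann)
    return(do.call(rbind, lapply(seq_along(ids), function(i) {
      g <- ann$go[[i]]
      if (!length(g)) return(NULL)
      data.frame(feature = ids[i], go = g, stringsAsFactors = FALSE)
    })))
  }
  if (is.null(go_annotation)) stop("no GO annotation available")
  t2og <- list()
  for (og in ogIds(ogmap))
    for (t in unlist(ogMembers(ogmap, og), use.names = FALSE))
      t2og[[t]] <- og
  keep <- go_annotation$feature %in% names(t2og)
  data.frame(feature = unlist(t2og[go_annotation$feature[keep]],
                              use.names = FALSE),
             go = go_annotation$go[keep], stringsAsFactors = FALSE)
}
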