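## Synthetic leaf-gradient transcriptome generator with planted truth.
##
## The generator emulates the study design the analysis assumes: three
## grass species with different photosynthetic subtypes, four leaf
## segments along the developmental gradient (base S1 to tip S7), three
## pooled replicates per species x segment, orthogroups of variable copy
## number, negative-binomial counts, and a de novo assembly's warts
## (extra isoforms, redundant contigs, non-coding transcripts, junk
## below 1 cpm).

#' Construct a simulation configuration
#'
#' Returns a validated \linkS4class{SimConfig}. Defaults describe the
#' emulated study: 3 species (labelled by photosynthetic subtype), segments
#' S1/S3/S5/S7, 3 replicates, mostly single-copy orthogroups, and two
#' planted cross-species effects (the core C4-cycle orthogroups up in the
#' C4 species at the leaf tip; core photorespiration orthogroups up in the
#' C3 species at the base).
#'
#' @param seed master seed; all stage streams derive from it.
#' @param n_og number of orthogroups.
#' @param species species labels.
#' @param segments ordered segment labels, base to tip.
#' @param n_reps replicates per species x segment.
#' @param copy_number_probs probabilities of 0,1,2,3 copies per species.
#' @param frac_species_absent fraction of orthogroups forced absent in one
#'   randomly chosen species.
#' @param baseline_logmean_range log2 range of orthogroup baseline weights.
#' @param dispersion_range negative-binomial dispersion range.
#' @param profile_weights named mixing weights of the profile classes.
#' @param profile_amplitude_range log2 amplitude range of non-flat profiles.
#' @param frac_pattern_divergent fraction of orthogroups with independently
#'   drawn per-species profile classes.
#' @param planted_deo data.frame (pathway, species, segment, log2fc); the
#'   pathway column may also name a single orthogroup ID.
#' @param frac_junk,frac_noncoding,isoform_rate assembly-noise rates.
#' @param library_size_range per-library depth range (log-uniform draws).
#' @param junk_cpm_range expected-cpm range of junk transcripts (< 1).
#' @param tf_frac fraction of orthogroups flagged as transcription factors.
#' @param orf_min_len minimum ORF length in nt for the coding label.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      n_og = 500L,
                      species = c("C3", "PK", "C4"),
                      segments = c("S1", "S3", "S5", "S7"),
                      n_reps = 3L,
                      copy_number_probs = c("0" = 0.05, "1" = 0.70,
                                            "2" = 0.18, "3" = 0.07),
                      frac_species_absent = 0.10,
                      baseline_logmean_range = c(4, 10),
                      dispersion_range = c(0.05, 0.2),
                      profile_weights = c(ascending = 0.40, descending = 0.25,
                                          peaked = 0.20, flat = 0.15),
                      profile_amplitude_range = c(2, 4),
                      frac_pattern_divergent = 0.25,
                      planted_deo = data.frame(
                        pathway = c("C4_cycle_core", "photorespiration_core"),
                        species = c("C4", "C3"),
                        segment = c("S7", "S1"),
                        log2fc = c(2, 2),
                        stringsAsFactors = FALSE),
                      frac_junk = 0.30,
                      frac_noncoding = 0.15,
                      isoform_rate = 0.8,
                      library_size_range = c(2e5, 5e5),
                      junk_cpm_range = c(0.01, 0.25),
                      tf_frac = 0.063,
                      orf_min_len = 100L) {
  if (nrow(planted_deo) && !all(planted_deo$species %in% species))
    stop("configuration error in 'planted_deo': unknown species label")
  new("SimConfig",
      seed = as.integer(seed), n_og = as.integer(n_og),
      species = species, segments = segments, n_reps = as.integer(n_reps),
      copy_number_probs = copy_number_probs,
      frac_species_absent = frac_species_absent,
      baseline_logmean_range = baseline_logmean_range,
      dispersion_range = dispersion_range,
      profile_weights = profile_weights,
      profile_amplitude_range = profile_amplitude_range,
      frac_pattern_divergent = frac_pattern_divergent,
      planted_deo = planted_deo,
      frac_junk = frac_junk, frac_noncoding = frac_noncoding,
      isoform_rate = isoform_rate,
      library_size_range = library_size_range,
      junk_cpm_range = junk_cpm_range,
      tf_frac = tf_frac, orf_min_len = as.integer(orf_min_len))
}

PROFILE_CLASSES <- c("ascending", "descending", "peaked", "flat")

## Deterministic unit shape of a profile class over nseg ordered segments.
profile_shape <- function(class, nseg) {
  switch(class,
         ascending  = seq(0, 1, length.out = nseg),
         descending = seq(1, 0, length.out = nseg),
         peaked     = {   # triangle peaking at the second segment
           p <- 2L
           ifelse(seq_len(nseg) <= p,
                  (seq_len(nseg) - 1) / (p - 1),
                  (nseg - seq_len(nseg)) / (nseg - p))
         },
         flat = rep(0, nseg),
         stop("unknown profile class: ", class))
}

#' Draw negative-binomial counts for a mean matrix
#'
#' Independent draws with variance \eqn{\mu + \phi \mu^2}; a dispersion of
#' zero degenerates to Poisson.
#'
#' @param mean_matrix feature x sample matrix of expected counts (>= 0).
#' @param dispersion per-feature dispersion phi (recycled along rows) or a
#'   full matrix; must be >= 0.
#' @param seed integer seed for the draw.
#' @return integer matrix of counts, same dimnames as \code{mean_matrix}.
#' @export
simulateCounts <- function(mean_matrix, dispersion, seed = 1L) {
  mean_matrix <- as.matrix(mean_matrix)
  if (any(mean_matrix < 0)) stop("negative mean in 'mean_matrix'")
  if (any(dispersion < 0)) stop("negative dispersion")
  phi <- if (is.matrix(dispersion)) dispersion
         else matrix(rep_len(dispersion, nrow(mean_matrix)),
                     nrow(mean_matrix), ncol(mean_matrix))
  set.seed(as.integer(seed))
  n <- length(mean_matrix)
  out <- numeric(n)
  mu <- as.vector(mean_matrix)
  ph <- as.vector(phi)
  pois <- ph == 0 | mu == 0
  out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois))
    out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / ph[!pois],
                                 mu = mu[!pois])
  matrix(out, nrow(mean_matrix), ncol(mean_matrix),
         dimnames = dimnames(mean_matrix))
}

## ---- sequence construction -------------------------------------------

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

## Coding transcript: random UTRs around ATG + sense codons + stop.
make_coding_seq <- function(n_codons) {
  paste0(random_nt(sample(20:80, 1)),
         "ATG", paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
                      collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1),
         random_nt(sample(20:80, 1)))
}

## Non-coding transcript: random sequence with every start codon scrubbed
## (forward ATG and reverse-strand starts, i.e. forward CAT), so no
## complete ORF exists on either strand. ATG -> ATA strictly reduces the
## G count and CAT -> CCT creates no new start motif, so the scrub
## terminates.
make_noncoding_seq <- function(len, min_len) {
  s <- random_nt(len)
  repeat {
    changed <- FALSE
    if (grepl("ATG", s, fixed = TRUE)) {
      s <- gsub("ATG", "ATA", s, fixed = TRUE); changed <- TRUE
    }
    if (grepl("CAT", s, fixed = TRUE)) {
      s <- gsub("CAT", "CCT", s, fixed = TRUE); changed <- TRUE
    }
    if (!changed) return(s)
  }
}

## Mutate ~rate of positions (keeps >= 1 - rate identity).
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  if (length(idx))
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

## ---- default pathway layout ------------------------------------------

## Pathway sizes mirror the study's curated lists (26 C4-cycle orthogroups,
## a similar-sized photorespiration and Calvin-Benson-Bassham set, smaller
## venation/suberin sets, and a handful of sink/source marker orthogroups).
default_pathway_sizes <- c(C4_cycle = 26, photorespiration = 24,
                           CBB_cycle = 26, venation = 20, suberin = 15,
                           sink_markers = 4, source_markers = 4)

assign_pathways <- function(shared_og) {
  sizes <- default_pathway_sizes
  need <- sum(sizes)
  if (length(shared_og) < need) {
    sc <- length(shared_og) / need
    sizes <- pmax(floor(sizes * sc), 2)   # pmax(x, 2) keeps the names
    while (sum(sizes) > length(shared_og)) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1
  }
  pool <- shared_og
  out <- list()
  for (p in names(sizes)) {
    take <- sample(pool, sizes[[p]])
    out[[p]] <- sort(take)
    pool <- setdiff(pool, take)
  }
  ## core sublists: first half of the parent list (planted-effect targets)
  out$C4_cycle_core <- out$C4_cycle[seq_len(ceiling(length(out$C4_cycle) / 2))]
  out$photorespiration_core <-
    out$photorespiration[seq_len(ceiling(length(out$photorespiration) / 2))]
  out
}

## ---- main generator --------------------------------------------------

#' Simulate a full cross-species leaf-gradient dataset
#'
#' Generates transcript sequences, per-species count and TPM matrices,
#' an orthogroup table (including two synthetic reference proteome columns
#' used for annotation transfer), reference annotation tables, a small GO
#' DAG with annotations, pathway membership lists, and the planted-truth
#' tables needed for recovery testing. Identical config (including seed)
#' yields identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with elements \code{config}, \code{transcripts} (per
#'   species \code{DNAStringSet} with mcols \code{gene_id}, \code{label}),
#'   \code{counts}, \code{tpm}, \code{lib_sizes}, \code{samples} (per
#'   species colData), \code{ogmap} (\linkS4class{OrthogroupMap} over focal
#'   + reference species), \code{ref_annotations}, \code{go_edges},
#'   \code{go_annotation}, \code{pathways}, and \code{truth} (tables
#'   \code{og_effects}, \code{pattern_class}, \code{pathway_membership},
#'   \code{transcript_labels}, \code{tf_flags}).
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  sp <- config@species
  seg <- config@segments
  nseg <- length(seg)
  nog <- config@n_og
  og_ids <- sprintf("OG%04d", seq_len(nog))

  ## -- structural stage: copies, absences, classes, pathways, TFs --
  set.seed(stage_seed(config@seed, "structure"))
  copies <- matrix(sample(0:3, nog * length(sp), replace = TRUE,
                          prob = config@copy_number_probs),
                   nog, length(sp), dimnames = list(og_ids, sp))
  n_absent <- floor(config@frac_species_absent * nog)
  if (n_absent > 0) {
    abs_og <- sample(seq_len(nog), n_absent)
    abs_sp <- sample(seq_along(sp), n_absent, replace = TRUE)
    copies[cbind(abs_og, abs_sp)] <- 0L
  }
  ## guard: an orthogroup absent everywhere is useless; give it one copy
  none <- rowSums(copies > 0) == 0
  copies[none, 1L] <- 1L
  shared <- og_ids[rowSums(copies > 0) == length(sp)]

  pathways <- assign_pathways(shared)
  tf <- stats::runif(nog) < config@tf_frac
  names(tf) <- og_ids

  ## profile classes: shared by default, independent for a divergent subset
  shared_class <- sample(PROFILE_CLASSES, nog, replace = TRUE,
                         prob = config@profile_weights[PROFILE_CLASSES])
  class_mat <- matrix(shared_class, nog, length(sp),
                      dimnames = list(og_ids, sp))
  n_div <- floor(config@frac_pattern_divergent * nog)
  if (n_div > 0) {
    div_og <- sample(seq_len(nog), n_div)
    for (i in div_og)
      class_mat[i, ] <- sample(PROFILE_CLASSES, length(sp), replace = TRUE,
                               prob = config@profile_weights[PROFILE_CLASSES])
  }
  ## marker orthogroups have their biology forced: sink markers (cell-cycle,
  ## sucrose synthase) fall base-to-tip, source markers (sucrose exporters,
  ## nitrate reductase) rise
  class_mat[pathways$sink_markers, ] <- "descending"
  class_mat[pathways$source_markers, ] <- "ascending"

  amp <- stats::runif(nog, config@profile_amplitude_range[1],
                      config@profile_amplitude_range[2])
  names(amp) <- og_ids
  base_log2 <- stats::runif(nog, config@baseline_logmean_range[1],
                            config@baseline_logmean_range[2])
  names(base_log2) <- og_ids
  ## per-copy baseline jitter and dispersion are properties of the
  ## ancestral gene copy, shared across species: species with equal copy
  ## number then have identical expected expression, so comparisons
  ## without planted effects are genuinely null
  copy_jitter <- matrix(stats::rnorm(nog * 3L, 0, 0.3), nog, 3L,
                        dimnames = list(og_ids, NULL))
  copy_phi <- matrix(stats::runif(nog * 3L, config@dispersion_range[1],
                                  config@dispersion_range[2]), nog, 3L,
                     dimnames = list(og_ids, NULL))

  ## planted effects, expanded to member orthogroups
  pd <- config@planted_deo
  eff <- array(0, dim = c(nog, length(sp), nseg),
               dimnames = list(og_ids, sp, seg))
  og_effects <- data.frame(og = character(), species = character(),
                           segment = character(), log2fc = numeric(),
                           stringsAsFactors = FALSE)
  if (nrow(pd)) {
    for (i in seq_len(nrow(pd))) {
      target <- if (pd$pathway[i] %in% names(pathways)) pathways[[pd$pathway[i]]]
                else if (pd$pathway[i] %in% og_ids) pd$pathway[i]
                else stop("configuration error in 'planted_deo': unknown pathway '",
                          pd$pathway[i], "'")
      bad <- target[copies[target, pd$species[i]] == 0]
      if (length(bad))   # keep the truth invariant: planted OG exist there
        copies[bad, pd$species[i]] <- 1L
      eff[target, pd$species[i], pd$segment[i]] <-
        eff[target, pd$species[i], pd$segment[i]] + pd$log2fc[i]
      og_effects <- rbind(og_effects, data.frame(
        og = target, species = pd$species[i], segment = pd$segment[i],
        log2fc = pd$log2fc[i], stringsAsFactors = FALSE))
    }
  }

  ## -- profile stage: per-gene structure and segment weights --
  set.seed(stage_seed(config@seed, "profiles"))
  genes <- list()   # per species: data.frame(gene, og, weight_log2, phi)
  for (s in sp) {
    rows <- list()
    for (i in seq_len(nog)) {
      k <- copies[i, s]
      if (k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        og = og_ids[i], copy = seq_len(k),
        weight_log2 = base_log2[i] - log2(k) + copy_jitter[i, seq_len(k)],
        phi = copy_phi[i, seq_len(k)],
        stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)
    g$gene_id <- sprintf("%s_g%05d", s, seq_len(nrow(g)))
    genes[[s]] <- g
  }

  ## segment-level log2 offsets per og x species
  offsets <- array(0, dim = c(nog, length(sp), nseg),
                   dimnames = list(og_ids, sp, seg))
  for (s in sp) for (i in seq_len(nog))
    offsets[i, s, ] <- amp[i] * profile_shape(class_mat[i, s], nseg) +
      eff[i, s, ]

  ## -- sequence stage --
  set.seed(stage_seed(config@seed, "sequences"))
  transcripts <- list(); labels_all <- list()
  for (s in sp) {
    g <- genes[[s]]
    n_main <- nrow(g)
    ids <- character(); seqs <- character(); gene_of <- character()
    lab <- character(); wt <- numeric(); phiv <- numeric(); ogv <- character()
    main_tid <- sprintf("%s_t1", g$gene_id)
    for (j in seq_len(n_main)) {
      cds <- sample(50:200, 1)
      sq <- make_coding_seq(cds)
      ids <- c(ids, main_tid[j]); seqs <- c(seqs, sq)
      gene_of <- c(gene_of, g$gene_id[j]); lab <- c(lab, "signal")
      wt <- c(wt, g$weight_log2[j]); phiv <- c(phiv, g$phi[j])
      ogv <- c(ogv, g$og[j])
      n_iso <- stats::rpois(1, config@isoform_rate)
      if (n_iso > 0) for (m in seq_len(n_iso)) {
        ## weakly expressed relative to the top isoform; the cap keeps the
        ## top isoform on top in TPM too (TPM is length-normalized and
        ## truncated isoforms keep >= 70% of the length)
        frac <- stats::runif(1, 0.05, 0.30)
        iso <- if (stats::runif(1) < 0.5) {
          len <- nchar(sq); a <- sample(seq_len(max(len %/% 8, 1)), 1)
          substr(sq, a, a + sample(ceiling(0.75 * len):(len - a), 1))
        } else mutate_seq(sq, 0.02)
        ids <- c(ids, sprintf("%s_t%d", g$gene_id[j], m + 1L))
        seqs <- c(seqs, iso); gene_of <- c(gene_of, g$gene_id[j])
        lab <- c(lab, "redundant-isoform")
        wt <- c(wt, g$weight_log2[j] + log2(frac))
        phiv <- c(phiv, g$phi[j]); ogv <- c(ogv, g$og[j])
      }
    }
    ## redundant contigs: near-copies of another gene's transcript that the
    ## redundancy collapse must absorb (distinct gene_id, not in any OG)
    n_red <- round(0.05 * n_main)
    if (n_red > 0) for (r in seq_len(n_red)) {
      gsrc <- sample(n_main, 1)                 # row of the gene table
      src <- match(main_tid[gsrc], ids)         # its main transcript
      gid <- sprintf("%s_r%04d", s, r)
      ids <- c(ids, paste0(gid, "_t1"))
      red <- if (stats::runif(1) < 0.5) seqs[src] else {
        len <- nchar(seqs[src])
        substr(seqs[src], sample(seq_len(max(len %/% 8, 1)), 1),
               len - sample(seq_len(max(len %/% 8, 1)), 1))
      }
      seqs <- c(seqs, red)
      gene_of <- c(gene_of, gid); lab <- c(lab, "redundant-isoform")
      wt <- c(wt, g$weight_log2[gsrc] - 2); phiv <- c(phiv, g$phi[gsrc])
      ogv <- c(ogv, NA_character_)
    }
    ## non-coding transcripts: expressed, but best ORF < orf_min_len
    n_nc <- round(config@frac_noncoding * n_main)
    if (n_nc > 0) for (r in seq_len(n_nc)) {
      gid <- sprintf("%s_nc%04d", s, r)
      ids <- c(ids, paste0(gid, "_t1"))
      seqs <- c(seqs, make_noncoding_seq(sample(200:600, 1),
                                         config@orf_min_len))
      gene_of <- c(gene_of, gid); lab <- c(lab, "noncoding")
      wt <- c(wt, stats::runif(1, 2, 6))
      phiv <- c(phiv, stats::runif(1, config@dispersion_range[1],
                                   config@dispersion_range[2]))
      ogv <- c(ogv, NA_character_)
    }
    ## junk: coding-looking but essentially unexpressed (target cpm < 1)
    n_junk <- round(config@frac_junk * n_main)
    junk_cpm <- exp(stats::runif(n_junk, log(config@junk_cpm_range[1]),
                                 log(config@junk_cpm_range[2])))
    if (n_junk > 0) for (r in seq_len(n_junk)) {
      gid <- sprintf("%s_j%04d", s, r)
      ids <- c(ids, paste0(gid, "_t1"))
      seqs <- c(seqs, make_coding_seq(sample(40:120, 1)))
      gene_of <- c(gene_of, gid); lab <- c(lab, "junk")
      wt <- c(wt, NA_real_)   # weight set from target cpm below
      phiv <- c(phiv, stats::runif(1, config@dispersion_range[1],
                                   config@dispersion_range[2]))
      ogv <- c(ogv, NA_character_)
    }
    info <- data.frame(transcript_id = ids, gene_id = gene_of, species = s,
                       og = ogv, label = lab, weight_log2 = wt,
                       phi = phiv, stringsAsFactors = FALSE)
    info$junk_cpm <- NA_real_
    info$junk_cpm[info$label == "junk"] <- junk_cpm
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ids
    S4Vectors::mcols(dss) <- S4Vectors::DataFrame(
      gene_id = gene_of, label = lab, og = ogv)
    transcripts[[s]] <- dss
    labels_all[[s]] <- info
  }

  ## -- library sizes --
  set.seed(stage_seed(config@seed, "libsizes"))
  samples <- list(); lib_sizes <- list()
  for (s in sp) {
    cd <- expand.grid(replicate = seq_len(config@n_reps), segment = seg,
                      stringsAsFactors = FALSE)[, 2:1]
    cd$species <- s
    cd <- cd[, c("species", "segment", "replicate")]
    cd$sample <- sprintf("%s_%s_r%d", cd$species, cd$segment, cd$replicate)
    ls <- exp(stats::runif(nrow(cd), log(config@library_size_range[1]),
                           log(config@library_size_range[2])))
    lib_sizes[[s]] <- stats::setNames(round(ls), cd$sample)
    samples[[s]] <- cd
  }

  ## -- count stage --
  set.seed(stage_seed(config@seed, "counts"))
  counts <- list(); tpm <- list()
  for (s in sp) {
    info <- labels_all[[s]]
    cd <- samples[[s]]
    nlib <- nrow(cd)
    ## per-segment linear weights for non-junk transcripts
    W <- matrix(0, nrow(info), nseg, dimnames = list(info$transcript_id, seg))
    sig <- !is.na(info$weight_log2)
    for (gi in seq_len(nseg)) {
      off <- rep(0, nrow(info))
      has_og <- !is.na(info$og)
      off[has_og] <- offsets[cbind(info$og[has_og], rep(s, sum(has_og)),
                                   rep(seg[gi], sum(has_og)))]
      W[sig, gi] <- 2^(info$weight_log2[sig] + off[sig])
    }
    ## junk weights solve expected-cpm targets within each segment
    jk <- info$label == "junk"
    for (gi in seq_len(nseg)) {
      Ssig <- sum(W[sig, gi])
      cpms <- info$junk_cpm[jk]
      W[jk, gi] <- cpms * Ssig / (1e6 - sum(cpms))
    }
    ## expected counts: library size x within-library relative abundance
    mu <- matrix(0, nrow(info), nlib,
                 dimnames = list(info$transcript_id, cd$sample))
    for (li in seq_len(nlib)) {
      w <- W[, match(cd$segment[li], seg)]
      mu[, li] <- lib_sizes[[s]][li] * w / sum(w)
    }
    cnt <- simulateCounts(mu, info$phi,
                          seed = stage_seed(config@seed, "counts") +
                            match(s, sp))
    counts[[s]] <- cnt
    len <- Biostrings::width(transcripts[[s]])
    rate <- cnt / len
    tpm[[s]] <- sweep(rate, 2, colSums(rate), "/") * 1e6
  }

  ## -- annotation stage: orthogroup table, references, GO --
  set.seed(stage_seed(config@seed, "annotation"))
  ref_sp <- c("REFA", "REFB")
  membership <- vector("list", nog); names(membership) <- og_ids
  for (i in seq_len(nog)) {
    m <- stats::setNames(vector("list", length(sp) + 2L), c(sp, ref_sp))
    for (s in sp) {
      g <- genes[[s]]
      m[[s]] <- sprintf("%s_t1", g$gene_id[g$og == og_ids[i]])
    }
    m$REFA <- if (stats::runif(1) < 0.85) sprintf("REFA_%04d", i) else character()
    m$REFB <- if (stats::runif(1) < 0.60) sprintf("REFB_%04d", i) else character()
    membership[[i]] <- m
  }
  ## ensure every orthogroup is annotatable from at least one reference
  for (i in seq_len(nog))
    if (!length(membership[[i]]$REFA) && !length(membership[[i]]$REFB) &&
        stats::runif(1) < 0.8)
      membership[[i]]$REFB <- sprintf("REFB_%04d", i)

  godag_tab <- build_go_layout(og_ids, pathways)
  ## reference annotation tables: transcript -> description/GO/TF
  ref_annotations <- list()
  for (r in ref_sp) {
    rows <- list()
    for (i in seq_len(nog)) {
      for (t in membership[[i]][[r]])
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = t,
          description = sprintf("%s homolog of %s", r, og_ids[i]),
          go = paste(godag_tab$og_terms[[og_ids[i]]], collapse = ","),
          tf = tf[[og_ids[i]]], stringsAsFactors = FALSE)
    }
    ref_annotations[[r]] <- do.call(rbind, rows)
  }
  ## transcript-level GO table over reference members
  go_annotation <- do.call(rbind, lapply(ref_sp, function(r) {
    a <- ref_annotations[[r]]
    do.call(rbind, lapply(seq_len(nrow(a)), function(j) {
      terms <- strsplit(a$go[j], ",")[[1]]
      if (!length(terms) || identical(terms, "")) return(NULL)
      data.frame(feature = a$transcript[j], go = terms,
                 stringsAsFactors = FALSE)
    }))
  }))

  ogmap <- new("OrthogroupMap", membership = membership,
               species = c(sp, ref_sp),
               annotation = S4Vectors::DataFrame(row.names = og_ids))

  pathway_tab <- do.call(rbind, lapply(names(pathways), function(p)
    data.frame(pathway = p, og = pathways[[p]], stringsAsFactors = FALSE)))

  truth <- list(
    og_effects = og_effects,
    pattern_class = do.call(rbind, lapply(sp, function(s) data.frame(
      og = og_ids, species = s, class = class_mat[, s],
      stringsAsFactors = FALSE, row.names = NULL))),
    pathway_membership = pathway_tab,
    transcript_labels = do.call(rbind, labels_all)[
      , c("transcript_id", "species", "gene_id", "og", "label")],
    tf_flags = data.frame(og = og_ids, tf = unname(tf),
                          stringsAsFactors = FALSE))
  rownames(truth$transcript_labels) <- NULL

  list(config = config, transcripts = transcripts, counts = counts,
       tpm = tpm, lib_sizes = lib_sizes, samples = samples,
       ogmap = ogmap, ref_annotations = ref_annotations,
       go_edges = godag_tab$edges, go_annotation = go_annotation,
       pathways = pathway_tab, truth = truth)
}

## Small GO layout: one root, four mid-level processes, twelve leaves (one
## leaf has two parents). Pathway orthogroups are annotated to matching
## leaves; the rest get random leaf terms.
build_go_layout <- function(og_ids, pathways) {
  root <- "GO:0008150"
  mids <- sprintf("GO:00001%02d", 1:4)
  leaves <- sprintf("GO:00002%02d", 1:12)
  edges <- rbind(
    data.frame(child = mids, parent = root, stringsAsFactors = FALSE),
    data.frame(child = leaves, parent = mids[ceiling(seq_along(leaves) / 3)],
               stringsAsFactors = FALSE),
    data.frame(child = leaves[12], parent = mids[1],
               stringsAsFactors = FALSE))
  ## map pathways onto dedicated leaves
  leaf_of <- c(C4_cycle = leaves[1], photorespiration = leaves[2],
               CBB_cycle = leaves[3], venation = leaves[4],
               suberin = leaves[5], sink_markers = leaves[6],
               source_markers = leaves[7])
  og_terms <- stats::setNames(vector("list", length(og_ids)), og_ids)
  for (og in og_ids)
    og_terms[[og]] <- sample(leaves[8:12], sample(1:2, 1))
  for (p in names(leaf_of)) for (og in pathways[[p]])
    og_terms[[og]] <- unique(c(leaf_of[[p]], og_terms[[og]]))
  list(edges = edges, og_terms = og_terms)
}

#' Write a simulated dataset to disk
#'
#' Emits the plain-text formats the pipeline consumes: per-species FASTA,
#' count and TPM TSV matrices (columns named species_segment_rep), the
#' orthogroup table (one comma-separated member column per species), GO
#' annotation and DAG-edge TSVs, pathway lists, the truth tables, and a
#' key=value config echo. Output is deterministic: identical simulations
#' write byte-identical files.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(sim$transcripts)) {
    Biostrings::writeXStringSet(sim$transcripts[[s]],
                                file.path(dir, paste0(s, "_transcripts.fasta")),
                                width = 70L)
    write_matrix_tsv(sim$counts[[s]],
                     file.path(dir, paste0(s, "_counts.tsv")),
                     id_col = "transcript_id")
    write_matrix_tsv(round(sim$tpm[[s]], 4),
                     file.path(dir, paste0(s, "_tpm.tsv")),
                     id_col = "transcript_id")
  }
  write_tsv(orthogroupTableFrame(sim$ogmap), file.path(dir, "orthogroups.tsv"))
  write_tsv(sim$go_edges, file.path(dir, "go_edges.tsv"))
  write_tsv(sim$go_annotation, file.path(dir, "go_annotation.tsv"))
  write_tsv(sim$pathways, file.path(dir, "pathways.tsv"))
  for (nm in names(sim$truth))
    write_tsv(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  cfg <- sim$config
  kv <- c(seed = cfg@seed, n_og = cfg@n_og,
          species = paste(cfg@species, collapse = ","),
          segments = paste(cfg@segments, collapse = ","),
          n_reps = cfg@n_reps)
  writeLines(paste0(names(kv), "=", unlist(kv)), file.path(dir, "config.txt"))
  invisible(dir)
}
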