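## Curation of a raw assembled transcript set into the high-confidence
## protein-coding set: top-isoform selection, redundancy collapse,
## single-best-ORF filtering, expression filtering, assembly statistics.
## All coordinates are 0-based half-open; strands are "+"/"-".

#' Keep the most expressed isoform of each gene
#'
#' @param expression named numeric vector of per-transcript expression
#'   (mean TPM across samples).
#' @param grouping named character vector mapping transcript IDs to gene
#'   (isoform-group) IDs.
#' @return character vector of kept transcript IDs (one per gene, the
#'   maximal mean TPM; ties broken lexicographically by transcript ID).
#' @export
selectTopIsoform <- function(expression, grouping) {
  miss <- setdiff(names(expression), names(grouping))
  if (length(miss))
    stop("input error: transcript(s) missing from grouping: ",
         paste(utils::head(miss, 3), collapse = ", "))
  tid <- names(expression)
  genes <- grouping[tid]
  ord <- order(genes, -expression, tid)   # per gene: max TPM, then lex ID
  keep <- tid[ord][!duplicated(genes[ord])]
  sort(keep)
}

## Unique k-mers of a sequence (character scalar).
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Collapse redundant transcripts
#'
#' Greedy longest-first clustering in the spirit of CD-HIT-EST: a sequence
#' is absorbed if it is an exact duplicate of a retained representative, an
#' exact substring of one, or if its k-mer containment identity against one
#' (shared unique k-mers / its own unique k-mers) reaches the threshold.
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param identity_threshold containment identity in (0, 1]; default 0.95.
#' @param k k-mer size (default 11).
#' @return character vector of representative transcript IDs.
#' @export
collapseRedundant <- function(sequences, identity_threshold = 0.95, k = 11L) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (!length(sequences)) return(character())
  if (is.null(names(sequences))) stop("sequences must be named")
  ord <- order(-nchar(sequences), names(sequences))  # longest first, lex ties
  sequences <- sequences[ord]
  index <- new.env(parent = emptyenv())   # k-mer -> indices of reps
  reps <- character(); repseq <- character()
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]; id <- names(sequences)[i]
    km <- seq_kmers(s, k)
    absorbed <- FALSE
    if (length(km)) {
      hits <- unlist(lapply(km, function(x) index[[x]]), use.names = FALSE)
      if (length(hits)) {
        tb <- tabulate(hits, nbins = length(reps))
        if (max(tb) / length(km) >= identity_threshold) absorbed <- TRUE
      }
    } else if (length(repseq)) {
      ## shorter than k: fall back to exact substring search
      absorbed <- any(vapply(repseq, function(r)
        grepl(s, r, fixed = TRUE), logical(1)))
    }
    if (!absorbed) {
      reps <- c(reps, id); repseq <- c(repseq, s)
      ri <- length(reps)
      for (x in km) index[[x]] <- c(index[[x]], ri)
    }
  }
  sort(reps)
}

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

## Reverse complement of a plain character sequence (N-aware).
revcomp_chr <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")

## Scan one frame of one strand; returns candidate ORFs as a data.frame of
## (start, len) in 0-based strand-local nt coordinates (span includes the
## stop codon). One ORF per stop: from the earliest usable start codon
## after the previous stop.
scan_frame <- function(codons, starts, require_start) {
  none <- list(start = integer(), len = integer())
  stop_idx <- which(codons %in% GENETIC_STOPS)
  if (!length(stop_idx)) return(none)
  if (require_start) {
    open_idx <- which(codons == "ATG")
  } else {
    ## first codon after each stop (and the frame's first codon)
    open_idx <- setdiff(c(1L, stop_idx + 1L), stop_idx)
    open_idx <- open_idx[open_idx <= length(codons)]
  }
  if (!length(open_idx)) return(none)
  ## first stop after each candidate start (a start is never a stop codon)
  nxt <- stop_idx[findInterval(open_idx, stop_idx) + 1L]
  ok <- !is.na(nxt)
  open_idx <- open_idx[ok]; nxt <- nxt[ok]
  if (!length(open_idx)) return(none)
  ## earliest start per stop: open_idx ascends and nxt is non-decreasing
  keep <- !duplicated(nxt)
  first <- open_idx[keep]; stop_at <- nxt[keep]
  list(start = starts[first] - 1L, len = (stop_at - first + 1L) * 3L)
}

#' Find the single best open reading frame
#'
#' Scans all six frames (both strands) for complete start-to-stop ORFs and
#' returns the longest whose length (in nt, stop codon included) reaches
#' \code{min_len_nt}. Ties are broken by forward strand first, then lower
#' frame, then lower start. Coordinates are 0-based half-open on the
#' reported strand.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param min_len_nt minimum ORF length in nt (default 100).
#' @param require_start require an ATG start codon (default TRUE).
#' @return a list \code{(start, end, strand, frame, length)}, or
#'   \code{NULL} when no qualifying ORF exists.
#' @export
findBestORF <- function(sequence, min_len_nt = 100L, require_start = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("input error: sequence contains non-nucleotide characters")
  best <- NULL
  n <- nchar(sequence)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp_chr(sequence)
    for (frame in 0:2) {
      if (n < frame + 3L) next
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      cand <- scan_frame(substring(s, starts, starts + 2L), starts,
                         require_start)
      if (!length(cand$len)) next
      j <- which.max(cand$len)   # within a frame, first max has lowest start
      if (is.null(best) || cand$len[j] > best$length)
        best <- list(start = cand$start[j], end = cand$start[j] + cand$len[j],
                     strand = strand, frame = frame, length = cand$len[j])
    }
  }
  if (is.null(best) || best$length < min_len_nt) NULL else best
}

#' Filter features by expression
#'
#' Keeps a feature iff its cpm reaches \code{min_cpm} in at least
#' \code{min_libraries} libraries; cpm is computed on raw library sizes
#' (no TMM), matching the filter's position before normalization.
#'
#' @param counts feature x sample count matrix.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @param min_cpm cpm threshold (default 1).
#' @param min_libraries minimum number of qualifying libraries (default 3).
#' @return character vector of kept feature IDs (input order).
#' @export
filterByExpression <- function(counts, lib_sizes = colSums(counts),
                               min_cpm = 1, min_libraries = 3L) {
  counts <- as.matrix(counts)
  if (min_libraries > ncol(counts))
    stop("configuration error: min_libraries exceeds the number of samples")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  cpmv <- sweep(counts, 2, lib_sizes, "/") * 1e6
  rownames(counts)[rowSums(cpmv >= min_cpm) >= min_libraries]
}

#' Assembly statistics
#'
#' @param lengths positive integer transcript lengths.
#' @return list with \code{n_transcripts}, \code{mean_length}, \code{n50}
#'   (largest L such that transcripts of length >= L hold at least half of
#'   the total bases).
#' @export
assemblyStats <- function(lengths) {
  if (!length(lengths)) stop("input error: empty length list")
  if (any(lengths <= 0)) stop("input error: lengths must be positive")
  sl <- sort(lengths, decreasing = TRUE)
  n50 <- sl[which(cumsum(as.numeric(sl)) >= sum(as.numeric(sl)) / 2)[1]]
  list(n_transcripts = length(lengths), mean_length = mean(lengths),
       n50 = n50)
}

#' Curate a raw transcript set
#'
#' Runs the full curation chain in order: top-isoform selection ->
#' redundancy collapse -> single-best-ORF filter -> expression filter.
#' The output of every stage is a subset of its input.
#'
#' @param sequences \code{DNAStringSet} with an mcols \code{gene_id} column
#'   (or a separate \code{grouping} vector).
#' @param counts transcript x sample raw counts (all input transcripts).
#' @param tpm transcript x sample TPM used for isoform ranking.
#' @param grouping optional named transcript -> gene_id map.
#' @param lib_sizes raw library sizes; default column sums of \code{counts}.
#' @param min_cpm,min_libraries expression-filter thresholds.
#' @param identity_threshold redundancy-collapse identity (default 0.95).
#' @param orf_min_len minimum ORF length in nt (default 100).
#' @param require_start require ATG starts in the ORF scan.
#' @return list with \code{kept} (final transcript IDs), \code{stages}
#'   (IDs surviving each stage), \code{orfs} (data.frame of best ORFs for
#'   kept transcripts), \code{stats} (assembly statistics of the final
#'   set) and \code{report} (per-stage survivor counts).
#' @export
curateTranscripts <- function(sequences, counts, tpm, grouping = NULL,
                              lib_sizes = colSums(counts),
                              min_cpm = 1, min_libraries = 3L,
                              identity_threshold = 0.95,
                              orf_min_len = 100L, require_start = TRUE) {
  if (is.null(grouping)) {
    mc <- S4Vectors::mcols(sequences)
    if (is.null(mc$gene_id)) stop("no grouping and no mcols gene_id")
    grouping <- stats::setNames(as.character(mc$gene_id), names(sequences))
  }
  mean_tpm <- rowMeans(as.matrix(tpm))[names(sequences)]
  s1 <- selectTopIsoform(stats::setNames(mean_tpm, names(sequences)), grouping)
  s2 <- collapseRedundant(sequences[s1], identity_threshold)
  orfs <- lapply(stats::setNames(s2, s2), function(id)
    findBestORF(as.character(sequences[[id]]), orf_min_len, require_start))
  s3 <- s2[!vapply(orfs, is.null, logical(1))]
  s4 <- intersect(filterByExpression(counts[s3, , drop = FALSE],
                                     lib_sizes = lib_sizes,
                                     min_cpm = min_cpm,
                                     min_libraries = min_libraries), s3)
  orf_tab <- do.call(rbind, lapply(s4, function(id) {
    o <- orfs[[id]]
    data.frame(transcript_id = id, start = o$start, end = o$end,
               strand = o$strand, frame = o$frame, length = o$length,
               stringsAsFactors = FALSE)
  }))
  list(kept = s4,
       stages = list(input = names(sequences), top_isoform = s1,
                     nonredundant = s2, coding = s3, expressed = s4),
       orfs = orf_tab,
       stats = assemblyStats(Biostrings::width(sequences[s4])),
       report = data.frame(
         stage = c("input", "top_isoform", "nonredundant", "coding",
                   "expressed"),
         n = c(length(sequences), length(s1), length(s2), length(s3),
               length(s4))))
}
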