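## Internal helpers shared across modules.

## Percentages are reported to one decimal, rounded half-to-even (base
## round() implements banker's rounding).
pct1 <- function(num, den) {
  if (den == 0) return(0)
  round(100 * num / den, 1)
}

## Derive a per-stage substream seed from the master seed. Offsets are
## fixed per stage so re-running a stage alone reproduces its stream.
## Kept strictly below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offs <- c(structure = 1L, profiles = 2L, counts = 3L, sequences = 4L,
            annotation = 5L, libsizes = 6L)
  if (!stage %in% names(offs)) stop("unknown simulation stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

## Deterministic TSV writer: fixed column order, no quoting, "\n" EOL.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

## Matrix -> TSV with an explicit id column (first), for diffable output.
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
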