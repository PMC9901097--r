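## Independent oracle implementations used to validate the package's own
## machinery. These deliberately take different routes (direct formulas,
## brute-force enumeration) from the code under test.

## Conditional NB exact p by direct log-gamma enumeration (the conditional
## split law depends only on the NB size parameters, not the mean).
oracle_exact_p <- function(yA, s, nA, nB, phi) {
  y <- 0:s
  if (phi == 0) {
    lp <- dbinom(y, s, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    lp <- lgamma(y + rA) - lgamma(y + 1) - lgamma(rA) +
      lgamma(s - y + rB) - lgamma(s - y + 1) - lgamma(rB)
  }
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  sum(pr[pr <= pr[yA + 1] * (1 + 1e-10)])
}

## Step-by-step TMM computation, written independently of tmmFactors.
oracle_tmm <- function(counts, lib = colSums(counts)) {
  q75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  r <- which.min(abs(q75 - mean(q75)))
  f <- sapply(seq_len(ncol(counts)), function(i) {
    ok <- counts[, i] > 0 & counts[, r] > 0
    y <- counts[ok, i]; yr <- counts[ok, r]
    M <- log2(y / lib[i]) - log2(yr / lib[r])
    A <- (log2(y / lib[i]) + log2(yr / lib[r])) / 2
    if (max(abs(M)) < 1e-6) return(1)
    w <- (lib[i] - y) / (lib[i] * y) + (lib[r] - yr) / (lib[r] * yr)
    n <- length(M)
    loM <- floor(0.30 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  })
  f / exp(mean(log(f)))
}

## Brute-force N50: test every candidate length L directly.
oracle_n50 <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand)
    if (sum(as.numeric(lengths[lengths >= L])) >= sum(as.numeric(lengths)) / 2)
      return(L)
  min(lengths)
}

## Brute-force best-ORF search: check every (strand, frame, start, stop)
## combination with a plain nested scan.
oracle_best_orf <- function(seq, min_len = 100, require_start = TRUE) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s),
                                       "")[[1]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    n <- nchar(s)
    for (frame in 0:2) {
      pos <- seq(frame + 1, n - 2, by = 3)
      if (length(pos) < 1 || pos[1] > n - 2) next
      cod <- substring(s, pos, pos + 2)
      open <- NA
      for (j in seq_along(cod)) {
        if (cod[j] %in% stops) {
          if (!is.na(open)) {
            len <- (j - open + 1) * 3
            if (is.null(best) || len > best$length)
              best <- list(start = pos[open] - 1, length = len,
                           strand = strand, frame = frame)
          }
          open <- NA
        } else if (is.na(open) && (!require_start || cod[j] == "ATG")) {
          open <- j
        }
      }
    }
  }
  if (is.null(best) || best$length < min_len) NULL else best
}

## k-mer containment identity by direct enumeration.
oracle_containment <- function(q, r, k = 11) {
  km <- function(s) unique(substring(s, 1:(nchar(s) - k + 1),
                                     1:(nchar(s) - k + 1) + k - 1))
  a <- km(q)
  length(intersect(a, km(r))) / length(a)
}

## Upper-tail hypergeometric by direct summation.
oracle_hyper <- function(k, K, n, N)
  sum(dhyper(k:min(K, n), K, N - K, n))

## Two-group NB count simulation used across DE tests: group B columns get
## the planted log2 effects (de vector), library sizes are log-uniform.
sim_two_group <- function(seed, n_feat = 500, n = 3, phi = 0.1,
                          frac_de = 0, log2fc = 2) {
  set.seed(seed)
  base <- 2^runif(n_feat, 5, 9)
  lib <- exp(runif(2 * n, log(2e5), log(5e5)))
  mu <- outer(base / sum(base), lib)
  de <- rep(0, n_feat)
  if (frac_de > 0) {
    idx <- sample(n_feat, round(frac_de * n_feat))
    de[idx] <- sample(c(-log2fc, log2fc), length(idx), replace = TRUE)
    mu[, (n + 1):(2 * n)] <- mu[, (n + 1):(2 * n)] * 2^de
  }
  dimnames(mu) <- list(paste0("g", seq_len(n_feat)),
                       paste0("s", seq_len(2 * n)))
  list(counts = simulateCounts(mu, phi, seed = seed + 1000), de = de,
       grpA = paste0("s", 1:n), grpB = paste0("s", (n + 1):(2 * n)))
}

## Small simulated dataset shared by slower tests (built once per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateDataset(simConfig(seed = 101, n_og = 150))
    cache
  }
})

## Orthogroup table written to a temp TSV for parser tests.
write_og_table <- function(rows, species = c("spA", "spB", "spC")) {
  path <- tempfile(fileext = ".tsv")
  df <- as.data.frame(do.call(rbind, lapply(rows, matrix, nrow = 1)),
                      stringsAsFactors = FALSE)
  colnames(df) <- c("og_id", species)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
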