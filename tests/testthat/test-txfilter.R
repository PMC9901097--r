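test_that("top-isoform selection keeps the most expressed isoform", {
  expr <- c(t1 = 5.0, t2 = 1.2, u1 = 3.0)
  grp <- c(t1 = "g1", t2 = "g1", u1 = "g2")
  expect_equal(selectTopIsoform(expr, grp), c("t1", "u1"))
  ## single-isoform gene passes through; ties go to the lexicographic ID
  expect_equal(selectTopIsoform(c(ta = 2, tb = 2), c(ta = "g", tb = "g")),
               "ta")
  expect_error(selectTopIsoform(c(tx = 1), c(ty = "g")), "missing")
})

test_that("redundancy collapse absorbs duplicates, substrings and near-identical sequences", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  ## exact duplicate
  expect_equal(collapseRedundant(c(a = base, b = base)), "a")
  ## exact substring of a retained representative
  expect_equal(collapseRedundant(c(long = base,
                                   short = substr(base, 20, 79))), "long")
  ## 10% divergence at threshold 0.95: both retained, and the direct
  ## enumeration of the k-mer containment confirms it is far below 0.95
  div <- base
  pos <- seq(5, 95, by = 10)
  for (p in pos) substr(div, p, p) <- chartr("ACGT", "GTAC",
                                             substr(div, p, p))
  expect_lt(oracle_containment(div, base), 0.95)
  expect_setequal(collapseRedundant(c(a = base, b = div)), c("a", "b"))
  ## empty input is not an error
  expect_identical(collapseRedundant(character()), character())
  ## idempotence: collapsing the representatives changes nothing
  seqs <- c(a = base, b = div, c = substr(base, 10, 90))
  reps <- collapseRedundant(seqs)
  expect_identical(collapseRedundant(seqs[reps]), reps)
})

test_that("ORF finder handles the documented cases", {
  ## 9 nt ORF is below the 100 nt threshold
  expect_null(findBestORF("ATGAAATAA"))
  expect_equal(findBestORF("ATGAAATAA", min_len_nt = 9)$length, 9L)
  ## constructed 120 nt ORF (ATG + 38 sense codons + stop)
  set.seed(8)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))
  body <- paste(sample(setdiff(sense, "ATG"), 38, replace = TRUE),
                collapse = "")
  seq120 <- paste0("CC", "ATG", body, "TAA", "GG")
  orf <- findBestORF(seq120, min_len_nt = 100)
  expect_equal(orf$length, 120L)
  expect_equal(orf$start, 2L)
  expect_equal(orf$strand, "+")
  ## longest wins between a 120 nt and a 150 nt ORF
  body2 <- paste(sample(setdiff(sense, "ATG"), 48, replace = TRUE),
                 collapse = "")
  two <- paste0(seq120, "TTTT", "ATG", body2, "TGA")
  expect_equal(findBestORF(two, min_len_nt = 100)$length, 150L)
  expect_error(findBestORF("ATGXXTAA"), "non-nucleotide")
})

test_that("ORF finder agrees with the brute-force 6-frame oracle", {
  set.seed(19)
  for (i in 1:300) {
    n <- sample(30:600, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    got <- findBestORF(s, min_len_nt = 30)
    want <- oracle_best_orf(s, min_len = 30)
    if (is.null(want)) {
      expect_null(got, label = s)
    } else {
      expect_equal(got$length, want$length, label = s)
      expect_equal(got$strand, want$strand, label = s)
      expect_equal(got$start, want$start, label = s)
    }
  }
})

test_that("expression filter applies the cpm-in-libraries rule", {
  counts <- rbind(keep = c(2, 2, 2, 0, 0, 0),
                  drop = c(2, 2, 0, 0, 0, 0),
                  zero = c(0, 0, 0, 0, 0, 0))
  libs <- rep(1e6, 6)
  kept <- filterByExpression(counts, libs, min_cpm = 1, min_libraries = 3)
  expect_equal(kept, "keep")
  expect_error(filterByExpression(counts, libs, min_libraries = 7),
               "configuration error")
  ## idempotence
  expect_equal(filterByExpression(counts[kept, , drop = FALSE], libs,
                                  min_libraries = 3), kept)
})

test_that("assembly statistics match the brute-force N50", {
  st <- assemblyStats(c(6, 5, 4, 3, 2))
  expect_equal(st$n50, 5)
  expect_equal(st$mean_length, 4)
  expect_equal(assemblyStats(rep(7L, 10))$n50, 7L)
  expect_error(assemblyStats(integer()), "empty")
  set.seed(23)
  for (i in 1:20) {
    lens <- sample(100:5000, 1000, replace = TRUE)
    expect_equal(assemblyStats(lens)$n50, oracle_n50(lens))
  }
})

test_that("curation runs its stages in order and only ever shrinks the set", {
  sim <- small_sim()
  cur <- curateTranscripts(sim$transcripts$PK, sim$counts$PK, sim$tpm$PK)
  st <- cur$stages
  expect_true(all(st$top_isoform %in% st$input))
  expect_true(all(st$nonredundant %in% st$top_isoform))
  expect_true(all(st$coding %in% st$nonredundant))
  expect_true(all(st$expressed %in% st$coding))
  expect_equal(cur$kept, st$expressed)
  ## every kept transcript has a recorded qualifying ORF
  expect_true(all(cur$orfs$length >= 100))
  expect_setequal(cur$orfs$transcript_id, cur$kept)
})
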