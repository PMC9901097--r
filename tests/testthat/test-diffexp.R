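test_that("cpm follows its definition", {
  expect_equal(unname(cpm(matrix(100), 1e6)[1, 1]), 100)
  expect_equal(unname(cpm(matrix(100), 1e3)[1, 1]), 1e5)
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(unname(colSums(cpm(m))), c(1e6, 1e6))
  expect_error(cpm(m, c(0, 1)), "domain error")
})

test_that("TMM satisfies its identities and matches the step-by-step oracle", {
  set.seed(41)
  m <- matrix(rnbinom(500 * 4, mu = 100, size = 5), 500, 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  ## identical samples: all factors one
  ident <- m[, c(1, 1, 1, 1)]; colnames(ident) <- paste0("s", 1:4)
  expect_equal(unname(tmmFactors(ident)$factors), rep(1, 4))
  ## pure depth scaling absorbed by the library size
  depth <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  expect_equal(unname(tmmFactors(depth)$factors), c(1, 1))
  ## geometric-mean-one constraint
  f <- tmmFactors(m)$factors
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
  ## oracle equivalence on random matrices
  for (sd in 1:5) {
    set.seed(sd)
    x <- matrix(rnbinom(500 * 4, mu = 2^runif(500, 3, 10), size = 5),
                500, 4, dimnames = dimnames(m))
    x <- sweep(x, 2, c(1, 1.5, 0.7, 2), "*")
    expect_lt(max(abs(tmmFactors(x)$factors - oracle_tmm(x))), 1e-10)
  }
  expect_error(tmmFactors(m[, 1, drop = FALSE]), "two samples")
  expect_error(tmmFactors(cbind(m[, 1], 0)), "all-zero")
})

test_that("TMM agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(55)
  m <- matrix(rnbinom(800 * 6, mu = 2^runif(800, 2, 11), size = 8), 800, 6,
              dimnames = list(paste0("g", 1:800), paste0("s", 1:6)))
  ours <- tmmFactors(m)$factors
  theirs <- edgeR::calcNormFactors(edgeR::DGEList(counts = m))$samples$norm.factors
  expect_lt(max(abs(ours - theirs)), 1e-8)
})

test_that("dispersion estimation recovers the generating dispersion", {
  set.seed(9)
  mu <- matrix(rep(2^runif(50, 5, 9), 6), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  grp <- rep(c("A", "B"), each = 3)
  ## Poisson data: median estimate collapses toward the floor
  expect_lte(median(estimateDispersion(simulateCounts(mu, 0, seed = 1),
                                       grp)), 0.01)
  ## phi = 0.2 recovered within a factor of two
  est <- median(estimateDispersion(simulateCounts(mu, 0.2, seed = 2), grp))
  expect_gte(est, 0.1); expect_lte(est, 0.4)
  ## constant feature hits the floor
  const <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:4)))
  expect_equal(unname(estimateDispersion(const, c("A", "A", "B", "B"),
                                         rep(100, 4))), rep(1e-4, 3))
  expect_error(estimateDispersion(const[, 1, drop = FALSE], "A"),
               "configuration error")
})

test_that("exact test matches closed forms and the enumeration oracle", {
  ## n = 1 per group, phi = 0, split (10, 0): Binomial(10, 1/2)
  expect_equal(exactNBTest(10, 0, 0, 1e6, 1e6)$p_value, 2 * 0.5^10)
  ## observed split at the conditional mode with symmetric sizes: p = 1
  expect_equal(exactNBTest(c(5, 5), c(5, 5), 0.1,
                           rep(1e6, 2), rep(1e6, 2))$p_value, 1)
  ## enumeration oracle over a spread of totals and dispersions
  for (phi in c(0.01, 0.1, 0.5)) for (s in c(5, 17, 36)) for (yA in 0:s) {
    got <- exactNBTest(yA, s - yA, phi, 1e6, 1e6)$p_value
    expect_lt(abs(got - oracle_exact_p(yA, s, 1, 1, phi)), 1e-12)
  }
  ## unequal replicate numbers against the same oracle
  for (phi in c(0.1, 0.5)) for (yA in 0:20) {
    got <- exactNBTest(c(yA, 0, 0), c(20 - yA, 0), phi,
                       rep(1e6, 3), rep(1e6, 2))$p_value
    expect_lt(abs(got - oracle_exact_p(yA, 20, 3, 2, phi)), 1e-12)
  }
  expect_error(exactNBTest(c(-1, 2), c(1, 1), 0.1, rep(1, 2), rep(1, 2)),
               "negative")
})

test_that("exact test is symmetric and depth-scale invariant", {
  set.seed(12)
  for (i in 1:50) {
    a <- rnbinom(3, mu = 80, size = 10); b <- rnbinom(3, mu = 120, size = 10)
    la <- runif(3, 2e5, 5e5); lb <- runif(3, 2e5, 5e5)
    f <- exactNBTest(a, b, 0.1, la, lb)
    r <- exactNBTest(b, a, 0.1, lb, la)
    expect_identical(f$p_value, r$p_value)
    expect_equal(f$log2fc, -r$log2fc)
    ## scaling every library size by a constant changes no p-value
    sc <- exactNBTest(a, b, 0.1, 2 * la, 2 * lb)
    expect_identical(f$p_value, sc$p_value)
  }
})

test_that("BH adjustment matches hand arithmetic and the reference", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.3), 0.3)
  expect_error(bhFDR(c(0.5, 1.2)), "domain error")
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(2:200, 1))
    expect_equal(bhFDR(p), p.adjust(p, method = "BH"))
  }
  ## shrinking any p never reduces the rejection count
  p <- runif(100)
  q0 <- sum(bhFDR(p) < 0.05)
  p2 <- p; p2[7] <- p2[7] / 10
  expect_gte(sum(bhFDR(p2) < 0.05), q0)
})

test_that("null p-values are valid under matched dispersion", {
  fr <- vapply(1:5, function(sd) {
    d <- sim_two_group(sd)
    nf <- tmmFactors(d$counts)
    p <- vapply(seq_len(nrow(d$counts)), function(i)
      exactNBTest(d$counts[i, d$grpA], d$counts[i, d$grpB], 0.1,
                  nf$effective_lib_sizes[d$grpA],
                  nf$effective_lib_sizes[d$grpB])$p_value, numeric(1))
    mean(p < 0.05)
  }, numeric(1))
  expect_lte(mean(fr), 0.075)
  expect_gte(mean(fr), 0.025)
})

test_that("segment and species drivers behave on planted data", {
  sim <- small_sim()
  oe <- aggregateExpression(sim$counts, sim$ogmap,
                            species = c("C3", "PK", "C4"))
  shared <- sharedOrthogroups(sim$ogmap, c("C3", "PK", "C4"))
  ## identical groups (same segment against itself) yield no DEG
  sub <- ogSubsetSpecies(oe, "C3")
  null_tab <- degBetweenSegments(sub, c("S5", "S5"))
  expect_equal(sum(null_tab$significant), 0)
  expect_error(degBetweenSegments(sub, c("S1", "S9")), "unknown segment")
  ## the boundary rule is strict: |log2fc| <= 1 is never significant
  deg <- degBetweenSegments(sub, c("S1", "S3"))
  expect_false(any(deg$significant & abs(deg$log2fc) <= 1))
  expect_true(all(deg$direction[!deg$significant] == "ns"))
  ## planted C4-cycle effect at S7 recovered with the correct direction
  tf <- stats::setNames(sim$truth$tf_flags$tf, sim$truth$tf_flags$og)
  deo <- deoBetweenSpecies(oe, c("C3", "C4"), "S7", og_ids = shared,
                           tf_flags = tf)
  core <- sim$pathways$og[sim$pathways$pathway == "C4_cycle_core"]
  up_in_c4 <- deo$results$feature_id[deo$results$direction == "up_in_B"]
  expect_gte(mean(core %in% up_in_c4), 0.70)
  expect_error(deoBetweenSpecies(oe, c("C3", "C4"), "S9"), "missing")
  ## TF summary arithmetic on a constructed table
  fake <- data.frame(feature_id = paste0("OG", 1:2757),
                     significant = TRUE)
  flags <- stats::setNames(rep(c(TRUE, FALSE), c(151, 2757 - 151)),
                           fake$feature_id)
  expect_equal(tfSummary(fake, flags)$pct_tf, 5.5)
})

test_that("power and false positives stay in band with estimated dispersion", {
  res <- vapply(1:5, function(sd) {
    d <- sim_two_group(sd, frac_de = 0.1, log2fc = 2)
    nf <- tmmFactors(d$counts)
    phis <- estimateDispersion(d$counts, rep(c("A", "B"), each = 3),
                               nf$effective_lib_sizes)
    out <- t(vapply(seq_len(nrow(d$counts)), function(i) {
      r <- exactNBTest(d$counts[i, d$grpA], d$counts[i, d$grpB], phis[i],
                       nf$effective_lib_sizes[d$grpA],
                       nf$effective_lib_sizes[d$grpB])
      c(r$p_value, r$log2fc)
    }, numeric(2)))
    q <- bhFDR(out[, 1])
    sig <- q < 0.01 & abs(out[, 2]) > 1
    c(power = mean(sig[d$de != 0]),
      fpr = mean(sig[d$de == 0]))
  }, numeric(2))
  expect_gte(mean(res["power", ]), 0.70)
  ## false-positive rate among null features within twice the nominal level
  expect_lte(mean(res["fpr", ]), 0.02)
})
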