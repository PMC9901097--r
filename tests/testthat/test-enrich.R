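toy_universe <- sprintf("g%03d", 1:100)

toy_dag <- function() {
  edges <- data.frame(child = c("mid1", "mid2", "leafA", "leafB", "leafC"),
                      parent = c("root", "root", "mid1", "mid1", "mid2"))
  ann <- rbind(data.frame(feature = toy_universe[1:10], go = "leafA"),
               data.frame(feature = toy_universe[11:25], go = "leafB"),
               data.frame(feature = toy_universe[26:40], go = "leafC"),
               data.frame(feature = toy_universe[41:60], go = "mid2"))
  goDag(edges, ann)
}

test_that("the GO DAG applies the true-path rule and rejects cycles", {
  dag <- toy_dag()
  ## closure: parents inherit all descendant annotations
  expect_setequal(dag@annotated$mid1, toy_universe[1:25])
  expect_setequal(dag@annotated$root, toy_universe[1:60])
  expect_equal(unname(dag@depth[c("root", "mid1", "leafA")]), c(0L, 1L, 2L))
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(goDag(cyc, data.frame(feature = "g1", go = "a")), "cycle")
})

test_that("Fisher enrichment matches the hypergeometric enumeration", {
  dag <- toy_dag()
  ## a term annotating the entire universe is never enriched
  full <- goDag(data.frame(child = character(), parent = character()),
                data.frame(feature = toy_universe, go = "all"))
  expect_equal(unname(fisherGO(full, toy_universe[1:10], toy_universe)["all"]),
               1)
  ## empty overlap: upper tail from zero is 1
  p <- fisherGO(dag, toy_universe[61:70], toy_universe)
  expect_equal(unname(p["leafA"]), 1)
  ## overlap 5 of study 10 against a 10-feature term
  study <- c(toy_universe[1:5], toy_universe[61:65])
  p2 <- fisherGO(dag, study, toy_universe)
  expect_lt(abs(p2["leafA"] - oracle_hyper(5, 10, 10, 100)), 1e-12)
  ## random study sets against the enumeration oracle, universe <= 200
  set.seed(15)
  for (i in 1:25) {
    st <- sample(toy_universe, sample(3:30, 1))
    pp <- fisherGO(dag, st, toy_universe)
    for (term in names(pp)) {
      K <- length(dag@annotated[[term]])
      k <- length(intersect(dag@annotated[[term]], st))
      expect_lt(abs(pp[term] - oracle_hyper(k, K, length(st), 100)), 1e-12)
    }
  }
  expect_error(fisherGO(dag, c("zzz"), toy_universe), "not contained")
})

test_that("elim decorrelates parents from significant children", {
  dag <- toy_dag()
  ## all signal inside leafA: its parent's elim p rises above its classic p
  study <- toy_universe[1:10]
  classic <- fisherGO(dag, study, toy_universe)
  elim <- elimGO(dag, study, toy_universe, alpha = 0.01)
  expect_lt(classic["leafA"], 0.01)
  expect_identical(elim[["leafA"]], classic[["leafA"]])
  expect_gt(elim["mid1"], classic["mid1"])
  expect_gt(elim["root"], classic["root"])
  ## no significant child: identical to classic everywhere
  weak <- c(toy_universe[c(1, 11, 26, 41)], toy_universe[61:70])
  expect_equal(elimGO(dag, weak, toy_universe, alpha = 1e-6),
               fisherGO(dag, weak, toy_universe))
  ## flat DAG (no edges): elim has nothing to eliminate
  flat <- goDag(data.frame(child = character(), parent = character()),
                data.frame(feature = toy_universe[1:30],
                           go = rep(c("t1", "t2"), 15)))
  expect_equal(elimGO(flat, toy_universe[1:10], toy_universe),
               fisherGO(flat, toy_universe[1:10], toy_universe))
})

test_that("PCA decomposes, reconstructs, and orients deterministically", {
  ## rank-1: the single varying feature carries all variance
  m <- matrix(5, 10, 6, dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  m[3, ] <- c(1, 2, 3, 4, 5, 6)
  pr <- pcaLoadings(m, 2)
  expect_equal(pr$variance_explained[1], 1)
  expect_equal(abs(pr$loadings["f3", 1]), 1)
  expect_gt(pr$loadings["f3", 1], 0)   # sign convention
  ## duplicated samples score identically
  set.seed(21)
  x <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:6)))
  x2 <- cbind(x, dup = x[, 2]); colnames(x2) <- c(colnames(x), "dup")
  pr2 <- pcaLoadings(x2)
  expect_equal(pr2$scores["s2", ], pr2$scores["dup", ])
  ## full reconstruction of the centered matrix
  pr3 <- pcaLoadings(x)
  expect_lt(max(abs(pr3$loadings %*% t(pr3$scores) - (x - rowMeans(x)))),
            1e-8)
  ## variance fractions: in [0,1], non-increasing, permutation-invariant
  expect_true(all(diff(pr3$variance_explained) <= 1e-12))
  perm <- x[, sample(ncol(x))]
  expect_equal(pcaLoadings(perm)$variance_explained,
               pr3$variance_explained)
  expect_error(pcaLoadings(x, 99), "n_components")
})

test_that("top/bottom loading sets are sized by the tail fraction and disjoint", {
  set.seed(33)
  L <- setNames(sample(seq(-1, 1, length.out = 100)), paste0("f", 1:100))
  s <- topLoadingSets(L, 0.05)
  expect_length(s$top, 5); expect_length(s$bottom, 5)
  expect_length(intersect(s$top, s$bottom), 0)
  expect_true(all(L[s$top] > max(L[setdiff(names(L), c(s$top, s$bottom))])))
  ## all-equal loadings: degenerate but error-free and disjoint
  Leq <- setNames(rep(0.5, 40), paste0("f", 1:40))
  seq_sets <- topLoadingSets(Leq, 0.05)
  expect_gte(length(seq_sets$top), 1)
  expect_length(intersect(seq_sets$top, seq_sets$bottom), 0)
  expect_error(topLoadingSets(L, 0.7), "fraction")
  expect_warning(topLoadingSets(L[1:10], 0.05), "fewer")
})
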