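test_that("orthogroup table parsing follows the layout contract", {
  p <- write_og_table(list(c("OG1", "t1,t2", "u1", "v1"),
                           c("OG2", "", "u2", "v2")))
  map <- parseOrthogroupTable(p)
  expect_equal(ogIds(map), c("OG1", "OG2"))
  cn <- copyNumber(map)
  expect_equal(unname(cn["OG1", ]), c(2L, 1L, 1L))
  ## empty cell: zero members, row retained
  expect_equal(unname(cn["OG2", ]), c(0L, 1L, 1L))
  ## member IDs deduplicated within a cell
  p2 <- write_og_table(list(c("OG1", "t1,t1", "u1", "v1")))
  expect_equal(ogMembers(parseOrthogroupTable(p2), "OG1", "spA"), "t1")
})

test_that("malformed orthogroup tables are rejected with format errors", {
  pdup <- write_og_table(list(c("OG1", "t1", "u1", "v1"),
                              c("OG1", "t2", "u2", "v2")))
  expect_error(parseOrthogroupTable(pdup), "duplicate orthogroup")
  pshared <- write_og_table(list(c("OG1", "t1", "u1", "v1"),
                                 c("OG2", "t1", "u2", "v2")))
  expect_error(parseOrthogroupTable(pshared), "t1")
})

test_that("aggregation sums member transcripts and conserves totals", {
  p <- write_og_table(list(c("OG1", "t1,t2", "u1", "v1"),
                           c("OG2", "t3", "u2", "v2")),
                      species = c("spA", "spB", "spC"))
  map <- parseOrthogroupTable(p)
  cnts <- list(
    spA = matrix(c(3, 7, 5, 1, 2, 9), 3, 2,
                 dimnames = list(c("t1", "t2", "t3"),
                                 c("spA_S1_r1", "spA_S1_r2"))),
    spB = matrix(c(4, 6, 8, 2), 2, 2,
                 dimnames = list(c("u1", "u2"),
                                 c("spB_S1_r1", "spB_S1_r2"))),
    spC = matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("v1", "v2"),
                                 c("spC_S1_r1", "spC_S1_r2"))))
  oe <- aggregateExpression(cnts, map)
  a <- SummarizedExperiment::assay(oe)
  ## multicopy orthogroup: the sum of its members
  expect_equal(unname(a["OG1", "spA_S1_r1"]), 10)
  ## single-copy orthogroup equals the member row
  expect_equal(unname(a["OG2", c("spA_S1_r1", "spA_S1_r2")]),
               unname(cnts$spA["t3", ]))
  ## totals conserved exactly per sample over member transcripts
  expect_identical(colSums(a)[colnames(cnts$spA)], colSums(cnts$spA))
  ## strict mode flags missing members
  cnts$spA <- cnts$spA[c("t1", "t3"), ]
  expect_error(aggregateExpression(cnts, map), "missing from counts")
  expect_s4_class(aggregateExpression(cnts, map, strict = FALSE),
                  "OGExpression")
})

test_that("annotation transfer honors the reference priority", {
  p <- write_og_table(list(c("OG1", "t1", "ra2,ra1", "rb1"),
                           c("OG2", "t2", "", "rb2"),
                           c("OG3", "t3", "", "")),
                      species = c("focal", "REFA", "REFB"))
  map <- parseOrthogroupTable(p)
  refs <- list(
    REFA = data.frame(transcript = c("ra1", "ra2"),
                      description = c("alpha", "beta"),
                      go = c("GO:1", "GO:2,GO:3"), tf = c(TRUE, FALSE)),
    REFB = data.frame(transcript = c("rb1", "rb2"),
                      description = c("gamma", "delta"),
                      go = c("GO:4", ""), tf = c(FALSE, TRUE)))
  ann <- ogAnnotation(transferAnnotation(map, refs, c("REFA", "REFB")))
  ## first-priority reference wins; lexicographically smallest member used
  expect_equal(ann["OG1", "source_species"], "REFA")
  expect_equal(ann["OG1", "description"], "alpha")
  expect_equal(ann["OG1", "go"][[1]], "GO:1")
  ## fallback to the second priority
  expect_equal(ann["OG2", "source_species"], "REFB")
  expect_true(ann["OG2", "tf"])
  ## no reference member: unannotated, not an error
  expect_true(is.na(ann["OG3", "source_species"]))
  expect_error(transferAnnotation(map, refs, character()), "non-empty")
})

test_that("annotation transfer is stable under input row permutation", {
  rows <- list(c("OG1", "t1", "ra1", ""), c("OG2", "t2", "ra2", "rb1"),
               c("OG3", "t3", "", "rb2"))
  refs <- list(
    REFA = data.frame(transcript = c("ra2", "ra1"),
                      description = c("b", "a"), go = c("", ""),
                      tf = c(FALSE, TRUE)),
    REFB = data.frame(transcript = c("rb2", "rb1"),
                      description = c("d", "c"), go = c("", ""),
                      tf = c(FALSE, FALSE)))
  a1 <- ogAnnotation(transferAnnotation(
    parseOrthogroupTable(write_og_table(rows,
                                        c("focal", "REFA", "REFB"))),
    refs, c("REFA", "REFB")))
  a2 <- ogAnnotation(transferAnnotation(
    parseOrthogroupTable(write_og_table(rev(rows),
                                        c("focal", "REFA", "REFB"))),
    rev(refs), c("REFA", "REFB")))
  for (og in rownames(a1)) {
    expect_identical(a1[og, "source_species"], a2[og, "source_species"])
    expect_identical(a1[og, "description"], a2[og, "description"])
  }
})

test_that("shared orthogroups require a member in every species", {
  p <- write_og_table(list(c("OG1", "t1", "u1", "v1"),
                           c("OG2", "t2", "", "v2")))
  map <- parseOrthogroupTable(p)
  expect_equal(sharedOrthogroups(map, c("spA", "spB", "spC")), "OG1")
  expect_equal(sharedOrthogroups(map, c("spA", "spC")), c("OG1", "OG2"))
  expect_error(sharedOrthogroups(map, "spX"), "unknown species")
  ## whitelist removes filtered-out members from consideration
  expect_equal(sharedOrthogroups(map, c("spA", "spB", "spC"),
                                 keep_features = c("t1", "u1")),
               character())
  ## on synthetic data the count matches the truth exactly
  sim <- small_sim()
  cn <- copyNumber(sim$ogmap)[, c("C3", "PK", "C4")]
  expect_equal(length(sharedOrthogroups(sim$ogmap, c("C3", "PK", "C4"))),
               sum(rowSums(cn > 0) == 3))
})
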