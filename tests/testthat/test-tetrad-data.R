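test_that("definitional tetrad classes are recovered", {
  te <- tetradsFromPairs(
    c("P1P1", "P1P1", "P2P2", "P2P2"),   # PD
    c("P1P1", "P2P2", "P1P2", "P2P1"),   # TT
    c("P1P2", "P1P2", "P2P1", "P2P1"))   # NPD
  cls <- classifyTetrads(te)
  expect_equal(unname(cls[, "L-R"]), c("PD", "TT", "NPD"))
  tal <- tallyIntervals(te)
  expect_equal(tal$PD, 1L)
  expect_equal(tal$TT, 1L)
  expect_equal(tal$NPD, 1L)
  expect_equal(tal$unscorable, 0L)
})

test_that("non-2:2 segregation and missing calls are unscorable", {
  te <- tetradsFromPairs(
    c("P1P1", "P1P1", "P1P2", "P2P1"),   # 3:1 at left marker
    c("P1P1", "--P1", "P2P2", "P2P2"))   # missing call
  expect_equal(unname(classifyTetrads(te)[, 1]),
               c("unscorable", "unscorable"))
})

test_that("classification is invariant under spore permutation and obeys the label-swap symmetry", {
  set.seed(42)
  cfg <- SimulationConfig(twoMarkerMap(), lengths_cM = 40,
                          n_tetrads = 25, seed = 421)
  te <- simulateTetrads(cfg)
  calls <- alleleCalls(te)
  flip <- function(v) chartr("12", "21", v)
  for (i in seq_len(nTetrads(te))) {
    cols <- (i - 1) * 4 + 1:4
    l <- calls["L", cols]; r <- calls["R", cols]
    base <- oracleClassify(l, r)
    for (rep in 1:5) {
      p <- sample(4)
      expect_identical(oracleClassify(l[p], r[p]), base)
      te2 <- tetradsFromPairs(paste0(l[p], r[p]))
      expect_identical(unname(classifyTetrads(te2)[1, 1]), base)
    }
    # swapping P1/P2 at both markers preserves the class
    teb <- tetradsFromPairs(paste0(flip(l), flip(r)))
    expect_identical(unname(classifyTetrads(teb)[1, 1]), base)
    # swapping at one marker exchanges PD and NPD, fixes TT
    teo <- tetradsFromPairs(paste0(flip(l), r))
    swapped <- c(PD = "NPD", NPD = "PD", TT = "TT",
                 unscorable = "unscorable")[base]
    expect_identical(unname(classifyTetrads(teo)[1, 1]),
                     unname(swapped))
  }
})

test_that("interval tallies conserve the tetrad count and match a per-tetrad oracle", {
  cfg <- nineMarkerConfig(150, seed = 7, spore_viability = 0.9,
                          conversion_rate = 0.02)
  te <- simulateTetrads(cfg)
  tal <- tallyIntervals(te)
  expect_true(all(tal$PD + tal$TT + tal$NPD + tal$unscorable ==
                    nTetrads(te)))
  expect_equal(tal$total, tal$PD + tal$TT + tal$NPD)
  # brute-force loop oracle
  calls <- alleleCalls(te)
  iv <- adjacentIntervals(te)
  for (j in seq_len(nrow(iv))) {
    ora <- table(factor(vapply(seq_len(nTetrads(te)), function(i) {
      cols <- (i - 1) * 4 + 1:4
      oracleClassify(calls[iv$left[j], cols], calls[iv$right[j], cols])
    }, character(1)), levels = c("PD", "TT", "NPD", "unscorable")))
    expect_equal(unname(unlist(tal[j, c("PD", "TT", "NPD",
                                        "unscorable")])),
                 unname(as.integer(ora)))
  }
})

test_that("zero map length yields no recombinant classes", {
  cfg <- SimulationConfig(twoMarkerMap(), lengths_cM = 0,
                          n_tetrads = 60, seed = 5)
  tal <- tallyIntervals(simulateTetrads(cfg))
  expect_equal(tal$TT, 0L)
  expect_equal(tal$NPD, 0L)
  expect_equal(tal$PD, 60L)
})

test_that("tetrad tables round-trip through the TSV dialect", {
  cfg <- nineMarkerConfig(40, seed = 12, spore_viability = 0.85,
                          conversion_rate = 0.03)
  te <- simulateTetrads(cfg)
  path <- tempfile(fileext = ".tsv")
  writeTetradTable(te, path)
  te2 <- readTetradTable(path, referenceMarkerMap(),
                         strain = strainLabel(te))
  expect_identical(alleleCalls(te2), alleleCalls(te))
  expect_identical(sporeInfo(te2), sporeInfo(te))
  expect_identical(markerInfo(te2), markerInfo(te))
})

test_that("malformed tetrad tables are rejected with informative errors", {
  mm <- twoMarkerMap()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("tetrad_id\tspore_id\tviable\tL\tR",
               "t1\ta\t1\tP1\tP1", "t1\tb\t1\tP1\tP1",
               "t1\tc\t1\tP2\tP2"), path)
  expect_error(readTetradTable(path, mm), "t1")
  writeLines(c("tetrad_id\tspore_id\tviable\tL\tX",
               "t1\ta\t1\tP1\tP1", "t1\tb\t1\tP1\tP1",
               "t1\tc\t1\tP2\tP2", "t1\td\t1\tP2\tP2"), path)
  expect_error(readTetradTable(path, mm), "undeclared marker")
})

test_that("intervals naming markers absent from a strain are skipped with a warning", {
  te <- tetradsFromPairs(c("P1P1", "P1P1", "P2P2", "P2P2"))
  iv <- rbind(adjacentIntervals(te),
              data.frame(interval = "R-THR1", left = "R",
                         right = "THR1", chromosome = "I"))
  expect_warning(cls <- classifyTetrads(te, iv), "R-THR1")
  expect_equal(colnames(cls), "L-R")
})

test_that("validity rules reject broken objects", {
  mm <- twoMarkerMap()
  calls <- matrix(c("P1", "P1", "P2", "P2", "P1", "P1", "P2", "P2"),
                  nrow = 2, dimnames = list(c("L", "R"), NULL))
  expect_error(
    TetradExperiment(calls, mm, tetrad_id = c("t1", "t1", "t1", "t2"),
                     spore_id = c("a", "b", "c", "a"),
                     viable = rep(TRUE, 4)),
    "4 spores")
  bad <- calls; bad[1, 1] <- "p1"
  expect_error(TetradExperiment(bad, mm), "P1")
})
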