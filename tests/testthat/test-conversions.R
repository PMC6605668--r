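# nine markers, all-2:2 baseline tetrad, with selected loci overwritten
nineMarkerTetrad <- function(non22 = character(), class = "3:1") {
  mm <- referenceMarkerMap()
  calls <- matrix(rep(c("P1", "P1", "P2", "P2"), each = 1),
                  nrow = nrow(mm), ncol = 4, byrow = TRUE,
                  dimnames = list(mm$marker, NULL))
  cl <- rep(class, length.out = length(non22))
  for (i in seq_along(non22)) {
    calls[non22[i], ] <- switch(cl[i],
      "3:1" = c("P1", "P1", "P1", "P2"),
      "1:3" = c("P1", "P2", "P2", "P2"),
      "4:0" = rep("P1", 4),
      "0:4" = rep("P2", 4))
  }
  TetradExperiment(calls, mm)
}

test_that("clean tetrads produce no conversion events", {
  ev <- detectConversions(nineMarkerTetrad())
  expect_equal(nrow(ev), 0L)
})

test_that("single-locus non-2:2 segregation is one labelled event", {
  ev <- detectConversions(nineMarkerTetrad("CEN3", "3:1"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$markers, "CEN3")
  expect_equal(ev$classes, "3:1")
  ev <- detectConversions(nineMarkerTetrad("SPO13", "0:4"))
  expect_equal(ev$classes, "0:4")
})

test_that("adjacent non-2:2 loci merge into one event, non-adjacent stay separate", {
  # adjacent on chromosome III
  ev <- detectConversions(nineMarkerTetrad(c("CEN3", "MAT")))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$markers, "CEN3,MAT")
  expect_equal(ev$n_loci, 2L)
  # non-adjacent on the same chromosome
  ev <- detectConversions(nineMarkerTetrad(c("HIS4", "MAT")))
  expect_equal(nrow(ev), 2L)
  # last marker of III and first of VIII are not adjacent
  ev <- detectConversions(nineMarkerTetrad(c("HMR", "SPO11")))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$chromosome, c("III", "VIII"))
})

test_that("merged events equal maximal runs found by a brute-force oracle", {
  mm <- referenceMarkerMap()
  set.seed(99)
  for (rep in 1:40) {
    non <- mm$marker[runif(9) < 0.3]
    te <- nineMarkerTetrad(non, sample(c("3:1", "1:3", "4:0", "0:4"),
                                       max(1, length(non)),
                                       replace = TRUE))
    ev <- detectConversions(te)
    # oracle: run-length encoding of the non-2:2 indicator per chromosome
    runs <- 0L
    for (ch in unique(mm$chromosome)) {
      ind <- mm$marker[mm$chromosome == ch] %in% non
      runs <- runs + sum(rle(ind)$values)
    }
    expect_equal(nrow(ev), runs)
  }
})

test_that("detectConversions refuses tetrads with inviable spores", {
  te <- nineMarkerTetrad()
  cd <- sporeInfo(te)
  calls <- alleleCalls(te)
  calls[, 4] <- NA_character_
  bad <- TetradExperiment(calls, referenceMarkerMap(),
                          tetrad_id = cd$tetrad_id,
                          spore_id = cd$spore_id,
                          viable = c(TRUE, TRUE, TRUE, FALSE))
  expect_error(detectConversions(bad), "viable")
})

test_that("conversion filter keeps 4-viable tetrads with at most two merged events", {
  mm <- referenceMarkerMap()
  clean <- nineMarkerTetrad()
  three <- nineMarkerTetrad(c("HIS4", "MAT", "HMR"))       # 3 events
  twoadj <- nineMarkerTetrad(c("CEN3", "MAT", "SPO13"))    # 2 events
  stack <- function(tes) {
    calls <- do.call(cbind, lapply(tes, alleleCalls))
    TetradExperiment(calls, mm)
  }
  te <- stack(list(clean, three, twoadj))
  kept <- filterForConversionAnalysis(te)
  expect_equal(tetradNames(kept), c("t0001", "t0003"))
  # tetrad with an inviable spore is dropped regardless of events
  calls <- alleleCalls(te)
  calls[, 8] <- NA_character_
  viable <- rep(TRUE, 12); viable[8] <- FALSE
  cd <- sporeInfo(te)
  te2 <- TetradExperiment(calls, mm, tetrad_id = cd$tetrad_id,
                          spore_id = cd$spore_id, viable = viable)
  expect_equal(tetradNames(filterForConversionAnalysis(te2)),
               c("t0001", "t0003"))
})
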