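test_that("crossover process has the right rate, dispersion and edge behaviour", {
  expect_equal(drawCrossovers(0, m = 0, n = 3),
               rep(list(numeric(0)), 3))
  expect_error(drawCrossovers(-0.1), ">= 0")
  set.seed(101)
  xo <- drawCrossovers(0.5, m = 0, n = 1e5)
  cnt <- lengths(xo)
  # Poisson with mean 2 * 0.5 = 1 on the bivalent
  expect_equal(mean(cnt), 1, tolerance = 3 * sqrt(1 / 1e5))
  expect_equal(var(cnt) / mean(cnt), 1, tolerance = 0.03)
  expect_true(all(unlist(xo) >= 0 & unlist(xo) < 0.5))
  expect_true(all(vapply(xo, function(p) !is.unsorted(p), TRUE)))
  # interference: renewal counts are under-dispersed
  set.seed(102)
  cnt4 <- lengths(drawCrossovers(0.5, m = 4, n = 1e5))
  expect_equal(mean(cnt4), 1, tolerance = 0.02)
  expect_lt(var(cnt4) / mean(cnt4), 1)
})

test_that("makeTetrad resolves crossovers deterministically", {
  mk <- twoMarkerMap(); mk$position_M <- c(0, 0.5)
  # no crossovers: parental ditype
  te <- makeTetrad(list(I = list(positions = numeric(0))), mk)
  expect_equal(unname(classifyTetrads(te)[1, 1]), "PD")
  # exactly one crossover inside the interval: always a tetratype
  for (a in 1:2) for (b in 3:4) {
    te <- makeTetrad(list(I = list(positions = 0.25,
                                   chromatids = cbind(a, b))), mk)
    expect_equal(unname(classifyTetrads(te)[1, 1]), "TT")
  }
  # two crossovers: 2-strand -> PD, 3-strand -> TT, 4-strand -> NPD
  two <- function(c1, c2) makeTetrad(list(I = list(
    positions = c(0.1, 0.3), chromatids = rbind(c1, c2))), mk)
  expect_equal(unname(classifyTetrads(two(c(1, 3), c(1, 3)))[1, 1]), "PD")
  expect_equal(unname(classifyTetrads(two(c(1, 3), c(1, 4)))[1, 1]), "TT")
  expect_equal(unname(classifyTetrads(two(c(1, 3), c(2, 4)))[1, 1]), "NPD")
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- nineMarkerConfig(60, seed = 77, spore_viability = 0.9,
                          conversion_rate = 0.02)
  a <- simulateTetrads(cfg)
  b <- simulateTetrads(cfg)
  expect_identical(alleleCalls(a), alleleCalls(b))
  f1 <- tempfile(); f2 <- tempfile()
  writeTetradTable(a, f1); writeTetradTable(b, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  c <- simulateTetrads(cfg, seed = 78)
  expect_false(identical(alleleCalls(a), alleleCalls(c)))
})

test_that("tetratype frequency matches the Poisson closed form at m = 0", {
  d <- 0.2                       # Morgans; bivalent mean is 2d
  cfg <- SimulationConfig(twoMarkerMap(), lengths_cM = 100 * d,
                          n_tetrads = 2e4, seed = 51)
  tal <- tallyIntervals(simulateTetrads(cfg))
  fTT <- tal$TT / tal$total
  lam <- 2 * d
  expected <- (2 / 3) * (1 - exp(-1.5 * lam))
  expect_equal(fTT, expected,
               tolerance = 3 * sqrt(expected * (1 - expected) / 2e4) /
                 expected)
  expect_gte(tal$PD, tal$NPD)    # PD always dominates NPD
})

test_that("viability and conversion overlays behave as configured", {
  cfg <- nineMarkerConfig(40, seed = 61)
  te <- simulateTetrads(cfg)
  # identity when viability 1 and conversion 0
  te2 <- applyConversionAndViability(te, cfg)
  expect_identical(alleleCalls(te2), alleleCalls(te))
  # viability 0: everything inviable and blanked
  cfg0 <- nineMarkerConfig(40, seed = 61, spore_viability = 0)
  te0 <- applyConversionAndViability(te, cfg0)
  expect_true(all(!sporeInfo(te0)$viable))
  expect_true(all(is.na(alleleCalls(te0))))
})

test_that("map length and interference are recovered from simulated data", {
  # 20 cM, no interference: Perkins recovers truth within 3 SE
  cfg <- SimulationConfig(twoMarkerMap(), lengths_cM = 20,
                          n_tetrads = 1e4, seed = 71)
  est <- mapEstimates(tallyIntervals(simulateTetrads(cfg)))
  expect_lt(abs(est$cM - 20), 3 * est$se_cM)
  # no interference: NPD ratio near 1
  expect_equal(est$npd_ratio, 1, tolerance = 0.2)
  # strong interference: ratio well below 1
  cfg4 <- SimulationConfig(twoMarkerMap(), lengths_cM = 20,
                           n_tetrads = 1e4, interference_m = 4L,
                           seed = 72)
  est4 <- mapEstimates(tallyIntervals(simulateTetrads(cfg4)))
  expect_lt(est4$npd_ratio, 1)
  expect_lt(est4$npd_ratio, est$npd_ratio)
})

test_that("short-interval recombinant fraction approaches the map length", {
  d <- 0.01                      # 1 cM
  cfg <- SimulationConfig(twoMarkerMap(), lengths_cM = 100 * d,
                          n_tetrads = 3e4, seed = 81)
  tal <- tallyIntervals(simulateTetrads(cfg))
  # per-chromatid recombinant fraction = (TT/2 + NPD) / n
  fr <- (tal$TT / 2 + tal$NPD) / tal$total
  expect_equal(fr, d, tolerance = 3 * sqrt(d / 3e4) / d)
})

test_that("config validation and YAML round trip", {
  expect_error(SimulationConfig(twoMarkerMap(), lengths_cM = 20,
                                n_tetrads = 10, spore_viability = 1.4),
               "viability")
  expect_error(SimulationConfig(twoMarkerMap(), lengths_cM = -5,
                                n_tetrads = 10), ">= 0")
  expect_error(SimulationConfig(twoMarkerMap(), lengths_cM = c(10, 10),
                                n_tetrads = 10), "one entry per")
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_tetrads: 25",
    "interference_m: 2",
    "spore_viability: 0.95",
    "conversion_rate: 0.01",
    "seed: 9",
    "chromosomes:",
    "  - name: III",
    "    markers: [HIS4, CEN3, MAT]",
    "    lengths_cM: [26.7, 20.1]",
    "  - name: VIII",
    "    markers: [SPO11, SPO13]",
    "    lengths_cM: [39.2]"), path)
  cfg <- readSimConfig(path)
  expect_s4_class(cfg, "SimulationConfig")
  expect_equal(cfg@n_tetrads, 25L)
  expect_equal(cfg@interference_m, 2L)
  expect_equal(cfg@markers$position_M,
               c(0, 0.267, 0.468, 0, 0.392))
  te <- simulateTetrads(cfg)
  expect_equal(nTetrads(te), 25)
})
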