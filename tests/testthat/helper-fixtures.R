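# fixtures built in code: tiny marker maps and hand-constructed tetrads

twoMarkerMap <- function()
  data.frame(marker = c("L", "R"), chromosome = "I", order_index = 1:2,
             phase = "P1")

# build a TetradExperiment from per-tetrad spore genotypes given as
# character vectors like c("P1P1","P1P1","P2P2","P2P2") over 2 markers
tetradsFromPairs <- function(..., markers = twoMarkerMap()) {
  tets <- list(...)
  calls <- do.call(cbind, lapply(tets, function(tt) {
    vapply(tt, function(s) c(substr(s, 1, 2), substr(s, 3, 4)),
           character(2))
  }))
  calls[calls == "--"] <- NA_character_
  rownames(calls) <- markers$marker
  TetradExperiment(calls, markers)
}

# a small multi-chromosome map with known genetic lengths
nineMarkerConfig <- function(n_tetrads, m = 0L, seed = 1L, ...) {
  SimulationConfig(referenceMarkerMap(),
                   lengths_cM = c(26.7, 20.1, 36.3, 22.9, 39.2, 7.6, 29.5),
                   interference_m = m, n_tetrads = n_tetrads,
                   seed = seed, ...)
}

# independent per-tetrad classifier used as an oracle: literal
# translation of the definitions, no shared code with the package
oracleClassify <- function(l, r) {
  if (anyNA(l) || anyNA(r)) return("unscorable")
  if (sum(l == "P1") != 2 || sum(r == "P1") != 2) return("unscorable")
  combos <- paste0(l, r)
  if (all(sort(combos) == c("P1P1", "P1P1", "P2P2", "P2P2"))) return("PD")
  if (all(sort(combos) == c("P1P2", "P1P2", "P2P1", "P2P1"))) return("NPD")
  if (length(unique(combos)) == 4) return("TT")
  "unscorable"
}
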