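#' Per-locus segregation tally
#'
#' Counts, for each marker locus, how many tetrads segregate 2:2, 3:1,
#' 1:3, 4:0 and 0:4 (P1:P2), plus the number of merged conversion
#' events ([detectConversions()]).  The dataset should already be
#' restricted to 4-spore-viable tetrads with at most two conversion
#' events ([filterForConversionAnalysis()]); tetrads with an inviable
#' spore are an error.  A tetrad with a missing call at a locus is
#' excluded from that locus's total.
#'
#' @param x a [TetradExperiment-class], pre-filtered.
#' @return data.frame with one row per locus: counts \code{n22},
#'   \code{n31}, \code{n13}, \code{n40}, \code{n04}, the locus total
#'   \code{total}, and percentages \code{pct_31_13}, \code{pct_40_04}
#'   of the two non-Mendelian classes.  The total number of tetrads and
#'   of merged events are attached as attributes \code{"n_tetrads"} and
#'   \code{"n_events"}.
#' @export
tallySegregation <- function(x) {
  stopifnot(is(x, "TetradExperiment"))
  cd <- sporeInfo(x)
  if (nTetrads(x) == 0L) stop("empty dataset")
  if (!all(cd$viable))
    stop("tallySegregation requires 4-spore-viable tetrads; ",
         "apply filterForConversionAnalysis() first")
  calls <- alleleCalls(x)
  tid <- factor(cd$tetrad_id, levels = tetradNames(x))
  counts <- matrix(0L, nrow(calls), 5L,
                   dimnames = list(rownames(calls),
                                   c("n04", "n13", "n22", "n31", "n40")))
  totals <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    byt <- split(calls[i, ], tid)
    nP1 <- vapply(byt, function(v)
      if (anyNA(v)) NA_integer_ else sum(v == "P1"), integer(1))
    nP1 <- nP1[!is.na(nP1)]
    totals[i] <- length(nP1)
    tt <- tabulate(nP1 + 1L, 5L)
    counts[i, ] <- tt
  }
  out <- data.frame(marker = rownames(calls),
                    counts[, c("n22", "n31", "n13", "n40", "n04"),
                           drop = FALSE],
                    total = totals, row.names = NULL)
  out$pct_31_13 <- 100 * (out$n31 + out$n13) / out$total
  out$pct_40_04 <- 100 * (out$n40 + out$n04) / out$total
  attr(out, "n_tetrads") <- nTetrads(x)
  attr(out, "n_events") <- nrow(detectConversions(x))
  out
}

#' Total non-Mendelian segregation and fold change vs control
#'
#' \code{nmsTotalPct} sums the per-locus non-2:2 percentages of a
#' [tallySegregation()] table (the "sum total percentage" summary of
#' conversion tables); \code{nmsFoldChange} is the ratio of that total
#' between a strain and a control.
#'
#' @param tally,control [tallySegregation()] outputs.
#' @return a single numeric value.
#' @export
nmsTotalPct <- function(tally) {
  sum(tally$pct_31_13 + tally$pct_40_04)
}

#' @rdname nmsTotalPct
#' @export
nmsFoldChange <- function(tally, control) {
  ctrl <- nmsTotalPct(control)
  if (ctrl <= 0) stop("control has no non-Mendelian events")
  nmsTotalPct(tally) / ctrl
}

#' Spore viability distribution
#'
#' Frequency of tetrads with four, three, two, one or zero viable
#' spores, and the overall percent spore viability
#' (\eqn{100 \sum viable / (4\, tetrads)}).
#'
#' @param x a [TetradExperiment-class].
#' @return list with \code{counts} (named integer vector, "4" .. "0"),
#'   \code{fractions} (same, as proportions) and \code{viability_pct}.
#' @export
viabilityDistribution <- function(x) {
  stopifnot(is(x, "TetradExperiment"))
  if (nTetrads(x) == 0L) stop("empty dataset")
  cd <- sporeInfo(x)
  nv <- vapply(split(cd$viable, cd$tetrad_id), sum, integer(1))
  counts <- vapply(4:0, function(k) sum(nv == k), integer(1))
  names(counts) <- as.character(4:0)
  list(counts = counts,
       fractions = counts / nTetrads(x),
       viability_pct = 100 * sum(cd$viable) / (4 * nTetrads(x)))
}

#' Sporulation efficiency
#'
#' Percent of cells that formed asci (2-, 3- or 4-spored) among all
#' cells scored.
#'
#' @param n2,n3,n4 counts of two-, three- and four-spore asci.
#' @param n_non count of cells that did not sporulate.
#' @return percent sporulated.
#' @export
#' @examples
#' sporulationEfficiency(10, 12, 35, 43)   # 57
sporulationEfficiency <- function(n2, n3, n4, n_non) {
  .checkCounts(n2 = n2, n3 = n3, n4 = n4, n_non = n_non)
  total <- n2 + n3 + n4 + n_non
  if (any(total == 0)) stop("no cells scored")
  100 * (n2 + n3 + n4) / total
}
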