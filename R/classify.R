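#' Genetic intervals between adjacent markers
#'
#' Builds the interval list used for classification: one interval per
#' pair of consecutive markers (by \code{order_index}) on each
#' chromosome.
#'
#' @param x a [TetradExperiment-class] or a marker map data.frame.
#' @return data.frame with columns \code{interval} (left-right name),
#'   \code{left}, \code{right}, \code{chromosome}.
#' @export
#' @examples
#' adjacentIntervals(referenceMarkerMap())
adjacentIntervals <- function(x) {
  mm <- if (is(x, "TetradExperiment")) markerInfo(x) else
    .normalizeMarkerMap(x)
  out <- do.call(rbind, lapply(split(mm, mm$chromosome), function(d) {
    d <- d[order(d$order_index), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    data.frame(left = d$marker[-nrow(d)], right = d$marker[-1L],
               chromosome = d$chromosome[1L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(interval = character(), left = character(),
                      right = character(), chromosome = character()))
  out <- data.frame(interval = paste(out$left, out$right, sep = "-"),
                    out, row.names = NULL)
  # preserve the chromosome order of the input map
  out[order(match(out$chromosome, unique(mm$chromosome))), ,
      drop = FALSE]
}

.checkIntervalDef <- function(intervals, mm) {
  for (i in seq_len(nrow(intervals))) {
    l <- intervals$left[i]; r <- intervals$right[i]
    il <- match(l, mm$marker); ir <- match(r, mm$marker)
    if (is.na(il) || is.na(ir)) next  # handled by caller (skip + warn)
    if (mm$chromosome[il] != mm$chromosome[ir])
      stop("interval ", intervals$interval[i],
           ": markers on different chromosomes")
    if (mm$order_index[il] >= mm$order_index[ir])
      stop("interval ", intervals$interval[i],
           ": left marker must precede right marker")
  }
  invisible(TRUE)
}

#' Classify tetrads for two-marker intervals
#'
#' For each tetrad and interval, assigns the classical two-point tetrad
#' class: \code{PD} (parental ditype; two spores of each parental
#' combination), \code{NPD} (non-parental ditype; two of each
#' recombinant combination), \code{TT} (tetratype; all four
#' combinations) or \code{unscorable}.  A tetrad is unscorable for an
#' interval when any spore is inviable or missing a call at either
#' marker, or when either marker does not segregate 2:2 (a
#' gene-conversion tetrad; those are tallied separately, see
#' [detectConversions()]).
#'
#' Intervals that reference markers absent from the dataset (e.g. a
#' strain that does not carry the full marker set) are skipped with a
#' warning rather than an error.
#'
#' @param x a [TetradExperiment-class].
#' @param intervals interval data.frame as from [adjacentIntervals()];
#'   defaults to all adjacent-marker intervals of \code{x}.
#' @return character matrix, tetrads x intervals, with values
#'   \code{"PD"}, \code{"TT"}, \code{"NPD"}, \code{"unscorable"}.
#' @export
classifyTetrads <- function(x, intervals = adjacentIntervals(x)) {
  stopifnot(is(x, "TetradExperiment"))
  mm <- markerInfo(x)
  present <- intervals$left %in% mm$marker &
    intervals$right %in% mm$marker
  if (any(!present)) {
    warning("skipping interval(s) with undeclared marker(s): ",
            paste(intervals$interval[!present], collapse = ", "))
    intervals <- intervals[present, , drop = FALSE]
  }
  .checkIntervalDef(intervals, mm)
  calls <- alleleCalls(x)
  tid <- sporeInfo(x)$tetrad_id
  tets <- unique(tid)
  res <- matrix(NA_character_, length(tets), nrow(intervals),
                dimnames = list(tets, intervals$interval))
  sporecols <- split(seq_len(ncol(calls)), factor(tid, levels = tets))
  for (j in seq_len(nrow(intervals))) {
    L <- calls[intervals$left[j], ]
    R <- calls[intervals$right[j], ]
    for (i in seq_along(tets)) {
      res[i, j] <- .classifyPair(L[sporecols[[i]]], R[sporecols[[i]]])
    }
  }
  res
}

# classify one tetrad from its four calls at the two interval markers
.classifyPair <- function(l, r) {
  if (anyNA(l) || anyNA(r)) return("unscorable")
  nl <- sum(l == "P1"); nr <- sum(r == "P1")
  if (nl != 2L || nr != 2L) return("unscorable")   # non-2:2
  k <- sum(l == "P1" & r == "P1")
  c("NPD", "TT", "PD")[k + 1L]
}

#' Tally tetrad classes per interval
#'
#' Sums the [classifyTetrads()] classes into per-interval PD/TT/NPD
#' counts.  The total \code{n = PD + TT + NPD} excludes unscorable
#' tetrads; \code{PD + TT + NPD + unscorable} equals the number of
#' tetrads for every interval.
#'
#' @inheritParams classifyTetrads
#' @return data.frame with columns \code{interval}, \code{chromosome},
#'   \code{PD}, \code{TT}, \code{NPD}, \code{total}, \code{unscorable}.
#' @export
#' @examples
#' cfg <- SimulationConfig(referenceMarkerMap(),
#'                         lengths_cM = c(27, 20, 36, 23, 39, 8, 30),
#'                         n_tetrads = 50, seed = 1)
#' tallyIntervals(simulateTetrads(cfg))
tallyIntervals <- function(x, intervals = adjacentIntervals(x)) {
  cls <- classifyTetrads(x, intervals)
  intervals <- intervals[intervals$interval %in% colnames(cls), ,
                         drop = FALSE]
  cnt <- function(what) vapply(colnames(cls), function(j)
    sum(cls[, j] == what), integer(1))
  out <- data.frame(interval = intervals$interval,
                    chromosome = intervals$chromosome,
                    PD = cnt("PD"), TT = cnt("TT"), NPD = cnt("NPD"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$total <- out$PD + out$TT + out$NPD
  out$unscorable <- cnt("unscorable")
  out
}
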