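#' Build a crossover map report from interval tallies
#'
#' Produces the standard tetrad-analysis table: one row per strain and
#' interval with PD/TT/NPD counts, Perkins cM and SE, NPD obs/exp
#' ratio and SE, per-chromosome map totals and (when a control strain
#' is named) percent-of-control columns.  Display conventions follow
#' the legacy linkage tables this package reproduces: cM and SE shown
#' with [displayRound()] to 1 decimal, ratios to 2 decimals, percents
#' as integers; per-chromosome totals are sums of the displayed cM
#' values, and percent columns are computed from displayed values.
#'
#' @param tallies data.frame of interval counts with columns
#'   \code{strain}, \code{interval}, \code{chromosome}, \code{PD},
#'   \code{TT}, \code{NPD} (e.g. several [tallyIntervals()] results
#'   stacked with a \code{strain} column, or a published count table).
#' @param control strain whose values define 100\%, or \code{NULL} for
#'   no normalization columns.
#' @param display round columns for display (default TRUE); with
#'   \code{FALSE}, unrounded statistics are returned and the
#'   sum/percent columns are computed from unrounded values.
#' @return data.frame report; \code{NA} in ratio columns corresponds to
#'   the "n.d." (not determined) entries of printed tables.
#' @export
#' @examples
#' counts <- referenceCrossoverCounts()
#' wt <- counts[counts$strain == "K842", ]
#' crossoverReport(wt)[, c("strain", "interval", "cM", "se_cM")]
crossoverReport <- function(tallies, control = NULL, display = TRUE) {
  need <- c("strain", "interval", "chromosome", "PD", "TT", "NPD")
  if (!all(need %in% colnames(tallies)))
    stop("tallies need columns: ", paste(need, collapse = ", "))
  if (nrow(tallies) == 0L) stop("empty tally table")
  if (!is.null(control) && !control %in% tallies$strain)
    stop("control strain '", control, "' not present")
  est <- mapEstimates(tallies[, need])
  est$total <- est$PD + est$TT + est$NPD
  rnd1 <- function(x) if (display) displayRound(x, 1) else x
  rnd2 <- function(x) if (display) roundHalfUp(x, 2) else x
  rnd0 <- function(x) if (display) roundHalfUp(x, 0) else x
  out <- est[, c("strain", "interval", "chromosome", "PD", "TT", "NPD",
                 "total")]
  out$cM <- rnd1(est$cM)
  out$se_cM <- rnd1(est$se_cM)
  out$npd_ratio <- rnd2(est$npd_ratio)
  out$npd_ratio_se <- rnd2(est$npd_ratio_se)
  # per-chromosome totals (sum of displayed cM -- table convention)
  out$cM_chr <- NA_real_
  for (s in unique(out$strain)) {
    sel <- out$strain == s
    sums <- chromosomeSum(est$cM[sel], est$chromosome[sel],
                          rounded = display)
    out$cM_chr[sel] <- roundHalfUp(sums[out$chromosome[sel]], 1)
  }
  if (!is.null(control)) {
    ctrl <- out[out$strain == control, ]
    idx <- match(out$interval, ctrl$interval)
    out$pct_control <-
      rnd0(normalizeToControl(out$cM, ctrl$cM[idx]))
    # chromosome percent compares sums over the intervals the strain
    # actually carries
    out$pct_chr <- NA_real_
    for (s in unique(out$strain)) {
      sel <- out$strain == s
      for (ch in unique(out$chromosome[sel])) {
        ss <- sel & out$chromosome == ch
        cc <- ctrl$chromosome == ch & ctrl$interval %in% out$interval[ss]
        out$pct_chr[ss] <- rnd0(normalizeToControl(
          sum(out$cM[ss]), sum(ctrl$cM[cc])))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Build a random-spore recombination report
#'
#' One row per strain and interval: percent recombinant spores with
#' binomial SE, per-chromosome totals (sums of the unrounded percents
#' -- the random-spore table convention) and percent-of-control
#' columns.
#'
#' @param counts data.frame with columns \code{strain},
#'   \code{interval}, \code{chromosome}, \code{r} (recombinant
#'   colonies) and \code{t} (total viable colonies).
#' @param control control strain label or \code{NULL}.
#' @param display round for display (default TRUE).
#' @return data.frame report.
#' @export
randomSporeReport <- function(counts, control = NULL, display = TRUE) {
  need <- c("strain", "interval", "chromosome", "r", "t")
  if (!all(need %in% colnames(counts)))
    stop("counts need columns: ", paste(need, collapse = ", "))
  if (nrow(counts) == 0L) stop("empty random-spore table")
  if (!is.null(control) && !control %in% counts$strain)
    stop("control strain '", control, "' not present")
  bad <- which(counts$r > counts$t)
  if (length(bad))
    stop("r exceeds t for ", counts$strain[bad[1]], " ",
         counts$interval[bad[1]])
  est <- randomSporePct(counts$r, counts$t)
  rnd1 <- function(x) if (display) roundHalfUp(x, 1) else x
  rnd0 <- function(x) if (display) roundHalfUp(x, 0) else x
  out <- counts[, need]
  out$pct_recombinant <- rnd1(est$pct_recombinant)
  out$se_pct <- rnd1(est$se_pct)
  out$pct_chr <- NA_real_
  for (s in unique(out$strain)) {
    sel <- out$strain == s
    sums <- chromosomeSum(est$pct_recombinant[sel],
                          out$chromosome[sel], rounded = FALSE)
    out$pct_chr[sel] <- rnd1(sums[out$chromosome[sel]])
  }
  if (!is.null(control)) {
    ctrl <- out[out$strain == control, ]
    idx <- match(out$interval, ctrl$interval)
    out$pct_control <- rnd0(normalizeToControl(
      out$pct_recombinant, ctrl$pct_recombinant[idx]))
    out$pct_chr_control <- NA_real_
    raw <- est$pct_recombinant
    for (s in unique(out$strain)) {
      sel <- out$strain == s
      for (ch in unique(out$chromosome[sel])) {
        ss <- sel & out$chromosome == ch
        cc <- counts$strain == control & counts$chromosome == ch &
          counts$interval %in% out$interval[ss]
        out$pct_chr_control[ss] <- rnd0(normalizeToControl(
          sum(raw[ss]), sum(raw[cc])))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Run the tetrad-analysis pipeline on genotype files
#'
#' Reads one tetrad TSV per strain, classifies and tallies all
#' adjacent-marker intervals, and writes a [crossoverReport()]-style
#' table.
#'
#' @param inputs named character vector of tetrad TSV paths; names are
#'   strain labels.
#' @param marker_map path to the marker map TSV ([readMarkerMap()]).
#' @param control control strain label (must be one of
#'   \code{names(inputs)}) or \code{NULL}.
#' @param out optional path for the report TSV.
#' @return the report data.frame, invisibly when \code{out} is given.
#' @export
runTetradAnalysis <- function(inputs, marker_map, control = NULL,
                              out = NULL) {
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop("'inputs' must be named by strain")
  mm <- readMarkerMap(marker_map)
  tl <- lapply(names(inputs), function(s) {
    te <- readTetradTable(inputs[[s]], mm, strain = s)
    cbind(strain = s, tallyIntervals(te))
  })
  rep <- crossoverReport(do.call(rbind, tl), control = control)
  if (!is.null(out)) {
    utils::write.table(rep, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "n.d.")
    return(invisible(rep))
  }
  rep
}

#' Run the random-spore pipeline on a count file
#'
#' @param input path to a TSV with columns \code{strain},
#'   \code{interval}, \code{chromosome}, \code{r}, \code{t}.
#' @inheritParams runTetradAnalysis
#' @return the report data.frame, invisibly when \code{out} is given.
#' @export
runRandomSporeAnalysis <- function(input, control = NULL, out = NULL) {
  counts <- utils::read.delim(input, stringsAsFactors = FALSE)
  rep <- randomSporeReport(counts, control = control)
  if (!is.null(out)) {
    utils::write.table(rep, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "n.d.")
    return(invisible(rep))
  }
  rep
}
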