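#' Perkins map distance
#'
#' The two-point map distance from tetrad class counts,
#' \deqn{cM = 100\,(TT/2 + 3\,NPD)/n,\qquad n = PD + TT + NPD,}
#' which corrects single-interval estimates for the double crossovers
#' revealed by non-parental ditypes.  All arguments are recycled, so a
#' whole column of interval counts can be converted at once.
#'
#' @param PD,TT,NPD non-negative integer counts of parental ditypes,
#'   tetratypes and non-parental ditypes.
#' @return map distance(s) in centiMorgans, unrounded (use
#'   [displayRound()] for table-style display).
#' @export
#' @examples
#' perkinsCM(344, 325, 6)            # 26.74 -> displayed 26.7
#' displayRound(perkinsCM(254, 255, 12))
perkinsCM <- function(PD, TT, NPD) {
  .checkCounts(PD = PD, TT = TT, NPD = NPD)
  n <- PD + TT + NPD
  if (any(n == 0))
    stop("undefined for n = PD + TT + NPD = 0")
  100 * (TT / 2 + 3 * NPD) / n
}

#' Standard error of the Perkins map distance
#'
#' Multinomial (delta-method) standard error of [perkinsCM()].  Because
#' the Perkins estimator is linear in the class counts, the formula
#' \deqn{SE = \frac{100}{\sqrt n}\sqrt{f_T/4 + 9 f_N -
#'   (f_T/2 + 3 f_N)^2},}
#' with \eqn{f_T = TT/n} and \eqn{f_N = NPD/n}, is the exact sampling
#' standard deviation under multinomial sampling of tetrad classes (not
#' merely a first-order approximation), as a multinomial bootstrap
#' confirms.
#'
#' @inheritParams perkinsCM
#' @return standard error(s) in centiMorgans.
#' @export
#' @examples
#' displayRound(perkinsSE(344, 325, 6))  # 1.4
perkinsSE <- function(PD, TT, NPD) {
  .checkCounts(PD = PD, TT = TT, NPD = NPD)
  n <- PD + TT + NPD
  if (any(n == 0))
    stop("undefined for n = PD + TT + NPD = 0")
  fT <- TT / n
  fN <- NPD / n
  (100 / sqrt(n)) * sqrt(fT / 4 + 9 * fN - (fT / 2 + 3 * fN)^2)
}

#' Papazian expected non-parental ditypes
#'
#' Expected NPD frequency under no crossover interference, predicted
#' from the observed tetratype frequency \eqn{f_T}:
#' \deqn{f_{NPD}^{exp} = \tfrac12\left[1 - f_T -
#'   (1 - 3 f_T/2)^{2/3}\right].}
#' The prediction is undefined when \eqn{f_T \ge 2/3} (the base of the
#' fractional power becomes non-positive), in which case \code{NA} is
#' returned.
#'
#' @inheritParams perkinsCM
#' @param what \code{"count"} (expected number, frequency times n) or
#'   \code{"frequency"}.
#' @return expected NPD count(s) or frequency(ies); \code{NA} where
#'   undefined.
#' @export
#' @examples
#' papazianExpectedNPD(344, 325, 6)   # about 31.3 expected NPDs
papazianExpectedNPD <- function(PD, TT, NPD,
                                what = c("count", "frequency")) {
  what <- match.arg(what)
  .checkCounts(PD = PD, TT = TT, NPD = NPD)
  n <- PD + TT + NPD
  if (any(n == 0))
    stop("undefined for n = PD + TT + NPD = 0")
  fT <- TT / n
  base <- 1 - 3 * fT / 2
  freq <- ifelse(base > 0, 0.5 * (1 - fT - base^(2 / 3)), NA_real_)
  if (what == "frequency") freq else freq * n
}

#' NPD ratio: observed over expected non-parental ditypes
#'
#' The crossover-interference statistic of two-point tetrad data: the
#' observed NPD count divided by the Papazian expectation
#' ([papazianExpectedNPD()]).  Ratios below 1 indicate positive
#' interference (fewer double crossovers than chance predicts).  The
#' ratio is reported as undefined (\code{NA}, printed "n.d.") when no
#' NPD was observed or when the expectation is undefined or zero.  The
#' standard error treats the observed count as Poisson:
#' \eqn{SE = \sqrt{NPD_{obs}}/NPD_{exp}}.
#'
#' @inheritParams perkinsCM
#' @return data.frame with columns \code{npd_expected},
#'   \code{npd_ratio} and \code{npd_ratio_se} (all \code{NA} when
#'   undefined).
#' @export
#' @examples
#' npdRatio(344, 325, 6)   # ratio 0.19, se 0.08
npdRatio <- function(PD, TT, NPD) {
  expected <- papazianExpectedNPD(PD, TT, NPD)
  n <- PD + TT + NPD          # recycling check happened above
  NPD <- rep_len(NPD, length(n))
  ok <- !is.na(expected) & expected > 0 & NPD > 0
  ratio <- ifelse(ok, NPD / expected, NA_real_)
  se <- ifelse(ok, sqrt(NPD) / expected, NA_real_)
  data.frame(npd_expected = expected, npd_ratio = ratio,
             npd_ratio_se = se)
}

#' Map estimates for a tally table
#'
#' Convenience wrapper applying [perkinsCM()], [perkinsSE()] and
#' [npdRatio()] to every row of an interval tally (as produced by
#' [tallyIntervals()] or taken from a published table).
#'
#' @param tally data.frame with columns \code{PD}, \code{TT},
#'   \code{NPD} (other columns are carried through).
#' @return \code{tally} with columns \code{cM}, \code{se_cM},
#'   \code{npd_expected}, \code{npd_ratio}, \code{npd_ratio_se}
#'   appended (unrounded).
#' @export
mapEstimates <- function(tally) {
  stopifnot(all(c("PD", "TT", "NPD") %in% colnames(tally)))
  out <- tally
  out$cM <- perkinsCM(tally$PD, tally$TT, tally$NPD)
  out$se_cM <- perkinsSE(tally$PD, tally$TT, tally$NPD)
  cbind(out, npdRatio(tally$PD, tally$TT, tally$NPD))
}

#' Random-spore recombination frequency
#'
#' Percent recombinant spores \eqn{100\,r/t} with binomial standard
#' error \eqn{100\sqrt{(r/t)(1 - r/t)/t}}, where \eqn{r} is the number
#' of colonies carrying a chromosome recombinant in the interval and
#' \eqn{t} the total viable colonies assessed.
#'
#' @param r recombinant colony count(s).
#' @param t total viable colony count(s); must satisfy
#'   \code{0 <= r <= t}, \code{t > 0}.
#' @return data.frame with columns \code{pct_recombinant} and
#'   \code{se_pct} (unrounded).
#' @export
#' @examples
#' randomSporePct(726, 2714)   # 26.8 percent
randomSporePct <- function(r, t) {
  .checkCounts(r = r, t = t)
  if (any(t == 0)) stop("t must be positive")
  if (any(r > t)) stop("r must not exceed t")
  p <- r / t
  data.frame(pct_recombinant = 100 * p,
             se_pct = 100 * sqrt(p * (1 - p) / t))
}

#' Per-chromosome sums of interval estimates
#'
#' Sums interval map distances (or random-spore percentages) within
#' chromosomes.  With \code{rounded = TRUE} (the convention of the
#' tetrad tables this package reproduces) each interval value is first
#' rounded for display with [displayRound()]; with
#' \code{rounded = FALSE} (the random-spore convention) the unrounded
#' values are summed.
#'
#' @param values numeric interval estimates.
#' @param chromosome chromosome of each interval.
#' @param rounded sum display-rounded values? (default \code{TRUE}).
#' @param digits display decimals used when \code{rounded} (default 1).
#' @return named numeric vector of per-chromosome sums (unrounded sum
#'   of the possibly rounded addends).
#' @export
#' @examples
#' chromosomeSum(perkinsCM(c(254, 265, 168, 282), c(255, 253, 317, 221),
#'                         c(12, 13, 29, 10)),
#'               rep("III", 4))   # 137.8
chromosomeSum <- function(values, chromosome, rounded = TRUE,
                          digits = 1) {
  stopifnot(length(values) == length(chromosome),
            length(values) > 0L)
  v <- if (rounded) displayRound(values, digits) else values
  vapply(split(v, factor(chromosome, levels = unique(chromosome))),
         sum, numeric(1))
}

#' Express a value as percent of a control
#'
#' @param value numeric value(s) (cM or percent recombinant).
#' @param control control value in the same units; must be positive.
#' @return \code{100 * value / control}, unrounded (tables display it
#'   rounded to an integer).
#' @export
#' @examples
#' roundHalfUp(normalizeToControl(13.9, 26.7))   # 52
normalizeToControl <- function(value, control) {
  if (!is.numeric(value) || !is.numeric(control))
    stop("inputs must be numeric")
  if (any(!is.na(control) & control <= 0))
    stop("control value must be positive")
  100 * value / control
}
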