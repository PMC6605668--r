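#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from
#' zero, the convention used throughout printed linkage tables (base R's
#' \code{round} rounds ties to even).  A tiny guard is added before
#' truncation so that values such as 0.285, which cannot be represented
#' exactly in binary, still round as a decimal reader expects.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector, rounded.
#' @export
#' @examples
#' roundHalfUp(0.285, 2)   # 0.29, where round() gives 0.28
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Display rounding for map distances
#'
#' Map distances and their standard errors are reported to one decimal
#' place.  Legacy linkage spreadsheets round an intermediate two-decimal
#' value rather than the full-precision estimate, so e.g. 50.947 cM is
#' displayed as 51.0 (via 50.95) and not 50.9.  \code{displayRound}
#' reproduces that convention: it rounds half away from zero at
#' \code{digits + 1} decimals first, then at \code{digits}.
#'
#' @param x numeric vector.
#' @param digits decimals in the displayed value (default 1).
#' @return numeric vector rounded for display.
#' @export
displayRound <- function(x, digits = 1) {
  roundHalfUp(roundHalfUp(x, digits + 1), digits)
}

# shared argument check: counts must be non-negative integers (or NA)
.checkCounts <- function(..., .allow_na = FALSE) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v))
      stop("'", nm[i], "' must be numeric", call. = FALSE)
    bad <- !is.na(v) & (v < 0 | v != floor(v))
    if (any(bad))
      stop("'", nm[i], "' must contain non-negative integer counts",
           call. = FALSE)
    if (!.allow_na && anyNA(v))
      stop("'", nm[i], "' contains NA", call. = FALSE)
  }
  invisible(TRUE)
}
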