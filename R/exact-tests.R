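#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed P value by the probability-mass method: with both
#' margins fixed, every table at least as improbable as the observed
#' one (point hypergeometric probability less than or equal to the
#' observed table's) contributes its probability to P.  This is the
#' convention of standard statistical software for two-sided 2x2 exact
#' tests.
#'
#' @param a,b,c,d cell counts (rows = groups, columns = outcome), or a
#'   2x2 matrix as \code{a}.
#' @return the two-tailed P value in (0, 1].
#' @export
#' @examples
#' fisherExactTwoTailed(23, 13, 29, 6)   # 0.107
fisherExactTwoTailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  .checkCounts(a = a, b = b, c = c, d = d)
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L,
            length(d) == 1L)
  if (a + b + c + d == 0) stop("at least one cell must be positive")
  m <- a + b          # margin of row 1
  n <- c + d          # margin of row 2
  k <- a + c          # margin of column 1
  xs <- max(0L, k - n):min(k, m)
  # point probabilities of all tables with these margins
  lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(lp)
  pobs <- p[xs == a]
  # relative tolerance guards against ties lost to floating point
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Rank-sum comparison of two independent samples.  For small samples
#' (combined n at most \code{exact_limit}) without ties the P value is
#' computed from the exact null distribution of the U statistic,
#' obtained by counting rank configurations; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_limit use the exact distribution when
#'   \code{length(x) + length(y)} does not exceed this and there are no
#'   ties (default 20).
#' @return the two-tailed P value in (0, 1].
#' @export
#' @examples
#' mannWhitneyTwoTailed(1:5, 6:10)   # complete separation, n = m = 5
mannWhitneyTwoTailed <- function(x, y, exact_limit = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nx + ny <= exact_limit) {
    U <- as.integer(round(U))
    K <- nx * ny
    cnt <- .uCounts(nx, ny)                  # counts of U = 0..nx*ny
    tot <- sum(cnt)
    p <- if (U > K / 2) {
      sum(cnt[(U:K) + 1L]) / tot             # P(U >= u)
    } else {
      sum(cnt[(0:U) + 1L]) / tot             # P(U <= u)
    }
    return(min(1, 2 * p))
  }
  mu <- nx * ny / 2
  tab <- table(r)
  sigma2 <- (nx * ny / 12) *
    ((nx + ny + 1) - sum(tab^3 - tab) / ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0) return(1)                 # all observations tied
  z <- U - mu
  z <- z - sign(z) * 0.5                     # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

# number of rank configurations giving each U value (coefficients of
# the Gaussian binomial), by the classical recurrence
# c(u; n, m) = c(u - m; n - 1, m) + c(u; n, m - 1)
.uCounts <- function(n, m) {
  K <- n * m
  a <- array(0, dim = c(K + 1L, n + 1L, m + 1L))
  a[1L, , ] <- 1                       # U = 0 always has one config
  for (i in seq_len(n)) for (j in seq_len(m)) for (u in 0:(i * j)) {
    a[u + 1L, i + 1L, j + 1L] <-
      (if (u >= j) a[u - j + 1L, i, j + 1L] else 0) +
      a[u + 1L, i + 1L, j]
  }
  a[, n + 1L, m + 1L]
}
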