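#' Simulation configuration for the meiosis model
#'
#' Describes one simulated cross: the marker map with genetic positions,
#' the crossover interference strength, the number of tetrads, and the
#' per-spore viability and per-locus gene-conversion probabilities.
#'
#' Crossovers are placed on the four-chromatid bundle (bivalent) by a
#' stationary gamma-renewal ("counting") process on the genetic scale:
#' inter-crossover distances are Gamma with integer shape
#' \eqn{m + 1} and mean \eqn{1/(2(m+1))} Morgans, so the bivalent sees
#' on average 2 crossovers per Morgan and each chromatid 1 per Morgan
#' (= the definition of the Morgan).  \code{m = 0} is the
#' interference-free Poisson case; larger \code{m} under-disperses
#' crossovers, suppressing nearby double events as meiotic interference
#' does.  Each crossover picks one chromatid of each homolog uniformly
#' and independently (no chromatid interference).
#'
#' @slot markers data.frame with columns \code{marker},
#'   \code{chromosome}, \code{order_index}, \code{phase},
#'   \code{position_M} (genetic position in Morgans, 0 at the first
#'   marker of each chromosome).
#' @slot interference_m non-negative integer interference parameter.
#' @slot n_tetrads number of tetrads to simulate.
#' @slot spore_viability probability that a spore is viable.
#' @slot conversion_rate per-locus, per-meiosis probability of a
#'   gene-conversion event.
#' @slot conversion_mix proportions of \code{3:1}, \code{1:3},
#'   \code{4:0}, \code{0:4} conversion classes (sums to 1).
#' @slot origin \code{"stationary"} (equilibrium first-arrival; no
#'   chromosome-end artifacts) or \code{"anchored"} (renewal process
#'   started at the left end).
#' @slot seed integer seed, or NA to leave the RNG stream alone.
#' @seealso [SimulationConfig()], [simulateTetrads()],
#'   [drawCrossovers()]
#' @export
setClass("SimulationConfig",
  representation(markers = "data.frame", interference_m = "integer",
                 n_tetrads = "integer", spore_viability = "numeric",
                 conversion_rate = "numeric", conversion_mix = "numeric",
                 origin = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  mk <- object@markers
  need <- c("marker", "chromosome", "order_index", "position_M")
  if (!all(need %in% colnames(mk)))
    msg <- c(msg, paste("markers needs columns:",
                        paste(need, collapse = ", ")))
  else {
    for (ch in unique(mk$chromosome)) {
      p <- mk$position_M[mk$chromosome == ch]
      o <- mk$order_index[mk$chromosome == ch]
      if (is.unsorted(p[order(o)], strictly = FALSE))
        msg <- c(msg, sprintf(
          "positions must be non-decreasing along chromosome '%s'", ch))
      if (any(p < 0)) msg <- c(msg, "positions must be >= 0")
    }
  }
  if (object@interference_m < 0L)
    msg <- c(msg, "interference_m must be >= 0")
  if (object@n_tetrads < 1L)
    msg <- c(msg, "n_tetrads must be positive")
  if (object@spore_viability < 0 || object@spore_viability > 1)
    msg <- c(msg, "spore_viability must be in [0, 1]")
  if (object@conversion_rate < 0 || object@conversion_rate > 1)
    msg <- c(msg, "conversion_rate must be in [0, 1]")
  mix <- object@conversion_mix
  if (length(mix) != 4L ||
      !identical(sort(names(mix)), sort(c("3:1", "1:3", "4:0", "0:4"))))
    msg <- c(msg, "conversion_mix needs entries 3:1, 1:3, 4:0, 0:4")
  else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "conversion_mix must be non-negative and sum to 1")
  if (!object@origin %in% c("stationary", "anchored"))
    msg <- c(msg, "origin must be 'stationary' or 'anchored'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimulationConfig-class
#' @param markers marker map data.frame (\code{marker},
#'   \code{chromosome}, \code{order_index}, optional \code{phase}).
#'   Either provide a \code{position_M} column or per-interval true
#'   lengths via \code{lengths_cM}.
#' @param lengths_cM true genetic lengths in centiMorgans of the
#'   adjacent-marker intervals, in [adjacentIntervals()] order.
#' @param interference_m,n_tetrads,spore_viability,conversion_rate,conversion_mix,origin,seed
#'   see slots.
#' @return a \code{SimulationConfig}.
#' @export
#' @examples
#' cfg <- SimulationConfig(referenceMarkerMap(),
#'   lengths_cM = c(26.7, 20.1, 36.3, 22.9, 39.2, 7.6, 29.5),
#'   n_tetrads = 100, seed = 42)
SimulationConfig <- function(markers, lengths_cM = NULL,
                             interference_m = 0L, n_tetrads,
                             spore_viability = 1, conversion_rate = 0,
                             conversion_mix = c("3:1" = 0.4, "1:3" = 0.4,
                                                "4:0" = 0.1, "0:4" = 0.1),
                             origin = c("stationary", "anchored"),
                             seed = NA_integer_) {
  origin <- match.arg(origin)
  mk <- .normalizeMarkerMap(markers)
  if (is.null(mk$position_M)) {
    if (is.null(lengths_cM))
      stop("provide either markers$position_M or lengths_cM")
    iv <- adjacentIntervals(mk)
    if (length(lengths_cM) != nrow(iv))
      stop("lengths_cM must have one entry per adjacent interval (",
           nrow(iv), ")")
    if (any(lengths_cM < 0)) stop("interval lengths must be >= 0")
    mk$position_M <- NA_real_
    for (ch in unique(mk$chromosome)) {
      sel <- mk$chromosome == ch
      mk$position_M[sel] <-
        cumsum(c(0, lengths_cM[iv$chromosome == ch])) / 100
    }
  }
  new("SimulationConfig", markers = mk,
      interference_m = as.integer(interference_m),
      n_tetrads = as.integer(n_tetrads),
      spore_viability = spore_viability,
      conversion_rate = conversion_rate,
      conversion_mix = conversion_mix[c("3:1", "1:3", "4:0", "0:4")],
      origin = origin, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d tetrads, m = %d (%s), viability %.2f, conversion %.3g\n",
    object@n_tetrads, object@interference_m, object@origin,
    object@spore_viability, object@conversion_rate))
  tot <- tapply(object@markers$position_M, object@markers$chromosome, max)
  cat("chromosomes:",
      paste(sprintf("%s (%.1f cM, %d markers)", names(tot), 100 * tot,
                    table(object@markers$chromosome)[names(tot)]),
            collapse = ", "), "\n")
})

#' Read a simulation configuration file
#'
#' YAML with top-level keys \code{n_tetrads}, \code{interference_m},
#' \code{spore_viability}, \code{conversion_rate},
#' \code{conversion_mix} (mapping with keys "3:1", "1:3", "4:0",
#' "0:4"), \code{origin}, \code{seed} and \code{chromosomes}: a list of
#' \code{\{name, markers, lengths_cM\}} blocks, where \code{lengths_cM}
#' has one entry per adjacent marker pair.
#'
#' @param path file path.
#' @return a [SimulationConfig-class].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$chromosomes)) stop("config needs a 'chromosomes' block")
  mk <- NULL; lens <- numeric()
  for (ch in y$chromosomes) {
    if (length(ch$lengths_cM) != length(ch$markers) - 1L)
      stop("chromosome ", ch$name,
           ": lengths_cM must have one entry per marker pair")
    mk <- rbind(mk, data.frame(marker = unlist(ch$markers),
                               chromosome = ch$name,
                               order_index = seq_along(ch$markers),
                               stringsAsFactors = FALSE))
    lens <- c(lens, unlist(ch$lengths_cM))
  }
  mix <- c("3:1" = 0.4, "1:3" = 0.4, "4:0" = 0.1, "0:4" = 0.1)
  if (!is.null(y$conversion_mix))
    mix[names(y$conversion_mix)] <- unlist(y$conversion_mix)
  SimulationConfig(mk, lengths_cM = lens,
    interference_m = y$interference_m %||% 0L,
    n_tetrads = y$n_tetrads %||% stop("config needs n_tetrads"),
    spore_viability = y$spore_viability %||% 1,
    conversion_rate = y$conversion_rate %||% 0,
    conversion_mix = mix,
    origin = y$origin %||% "stationary",
    seed = y$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw crossover positions on a bivalent
#'
#' Samples the crossover positions of \code{n} independent meioses for
#' a chromosome of genetic length \code{length_M} Morgans under the
#' gamma-renewal interference model (see
#' [SimulationConfig-class]).  With \code{m = 0} this is exactly a
#' homogeneous Poisson process of rate 2 per Morgan on the bivalent.
#' With \code{origin = "stationary"} the first event is drawn from the
#' equilibrium residual distribution (for integer shape, a Gamma whose
#' shape is uniform on \eqn{1..m+1}), making the process stationary.
#'
#' @param length_M chromosome length in Morgans (>= 0).
#' @param m non-negative integer interference parameter.
#' @param n number of meioses.
#' @param origin \code{"stationary"} or \code{"anchored"}.
#' @return list of \code{n} ascending numeric vectors of positions in
#'   \code{[0, length_M)}.
#' @export
#' @examples
#' set.seed(1)
#' lengths(drawCrossovers(0.5, m = 0, n = 5))
drawCrossovers <- function(length_M, m = 0L, n = 1L,
                           origin = c("stationary", "anchored")) {
  origin <- match.arg(origin)
  if (length_M < 0) stop("length_M must be >= 0")
  stopifnot(m >= 0, n >= 1)
  if (length_M == 0)
    return(rep(list(numeric(0)), n))
  k <- as.integer(m) + 1L
  beta <- 2 * k                       # events at rate 2 per Morgan
  first <- if (origin == "stationary") {
    stats::rgamma(n, shape = sample.int(k, n, replace = TRUE),
                  rate = beta)
  } else {
    stats::rgamma(n, shape = k, rate = beta)
  }
  K <- max(4L, ceiling(2 * length_M + 4 * sqrt(2 * length_M) + 4))
  cs <- matrix(0, n, K)
  cs[, 1L] <- first
  if (K > 1L) {
    g <- matrix(stats::rgamma(n * (K - 1L), shape = k, rate = beta),
                n, K - 1L)
    for (j in 2:K) cs[, j] <- cs[, j - 1L] + g[, j - 1L]
  }
  # rare rows that have not yet crossed the end get more events
  while (any(short <- cs[, ncol(cs)] < length_M)) {
    idx <- which(short)
    ext <- matrix(stats::rgamma(length(idx) * 4L, shape = k, rate = beta),
                  length(idx), 4L)
    ext[, 1L] <- cs[idx, ncol(cs)] + ext[, 1L]
    for (j in 2:4) ext[, j] <- ext[, j - 1L] + ext[, j]
    block <- matrix(Inf, n, 4L)
    block[idx, ] <- ext
    cs <- cbind(cs, block)
  }
  keep <- cs < length_M
  counts <- rowSums(keep)
  pos <- t(cs)[t(keep)]
  unname(split(pos, factor(rep(seq_len(n), counts),
                           levels = seq_len(n))))
}

# allele content (TRUE = P1) of the four meiotic products of one
# bivalent.  Strands 1,2 are the parent-1 sister chromatids and 3,4
# the parent-2 sisters; 'chromatids' names, for each crossover, the
# parent-1 strand (1 or 2) and parent-2 strand (3 or 4) involved.
# Each final product is the path that starts on one strand at the left
# telomere and switches to the partner strand at every crossover that
# involves the strand it is currently following; its allele at a
# marker is the parental origin of the strand it is on there.  This
# path construction guarantees that every exchange joins a P1- and a
# P2-carrying molecule at the exchange point (a single crossover in an
# interval always yields a tetratype).
.chromatidAlleles <- function(positions, chromatids, marker_pos) {
  o <- order(positions)
  xs <- positions[o]
  ch <- chromatids[o, , drop = FALSE]
  K <- length(xs)
  cur <- 1:4                          # strand each product is on
  curs <- matrix(0L, 4L, K + 1L)
  curs[, 1L] <- cur
  for (t in seq_len(K)) {
    i <- which(cur == ch[t, 1L])
    j <- which(cur == ch[t, 2L])
    cur[c(i, j)] <- cur[c(j, i)]
    curs[, t + 1L] <- cur
  }
  seg <- findInterval(marker_pos, xs)   # crossovers left of marker
  matrix(curs[, seg + 1L] <= 2L, nrow = 4L)
}

#' Assemble one tetrad from a chiasma realization
#'
#' Deterministically turns a realized set of crossovers into the four
#' spore genotypes: each crossover exchanges the marker content distal
#' to its position between the chosen non-sister chromatids, and the
#' four chromatids of each chromosome are dealt to the four spores
#' according to \code{assortment}.
#'
#' @param realization named list (one element per chromosome, names
#'   matching the chromosomes of \code{markers}); each element a list
#'   with \code{positions} (numeric), \code{chromatids} (matrix with
#'   one row per crossover: a value in 1:2 and one in 3:4) and
#'   optionally \code{assortment} (permutation of 1:4; default
#'   identity).
#' @param markers marker data.frame with \code{position_M} (see
#'   [SimulationConfig-class]).
#' @param tetrad_id identifier for the new tetrad.
#' @return a one-tetrad [TetradExperiment-class].
#' @export
makeTetrad <- function(realization, markers, tetrad_id = "t0001") {
  mk <- .normalizeMarkerMap(markers)
  if (is.null(mk$position_M))
    stop("markers need a position_M column")
  calls <- NULL
  for (ch in unique(mk$chromosome)) {
    sel <- mk$chromosome == ch
    rl <- realization[[ch]]
    if (is.null(rl)) rl <- list(positions = numeric(0))
    if (is.null(rl$chromatids))
      rl$chromatids <- matrix(integer(0), 0L, 2L)
    ass <- rl$assortment %||% 1:4
    A <- .chromatidAlleles(rl$positions, rl$chromatids,
                           mk$position_M[sel])
    A <- A[ass, , drop = FALSE]
    cc <- matrix(ifelse(t(A), "P1", "P2"), ncol = 4L,
                 dimnames = list(mk$marker[sel], NULL))
    calls <- rbind(calls, cc)
  }
  TetradExperiment(calls, mk,
                   tetrad_id = rep(tetrad_id, 4L),
                   spore_id = c("a", "b", "c", "d"),
                   viable = rep(TRUE, 4L))
}

#' Overlay gene conversion and spore death on tetrads
#'
#' Applies the stochastic post-processing of the simulator to an
#' existing [TetradExperiment-class]: each locus of each tetrad is
#' independently converted with probability \code{conversion_rate}
#' (class drawn from \code{conversion_mix}; a 3:1 or 1:3 event
#' overwrites one spore's call at the locus, a 4:0 or 0:4 event two),
#' then each spore is independently inviable with probability
#' \code{1 - spore_viability} (all its calls blanked).  With viability
#' 1 and conversion rate 0 this is the identity.
#'
#' @param x a [TetradExperiment-class] (4-viable, complete calls).
#' @param config a [SimulationConfig-class] (only the viability and
#'   conversion slots are used).
#' @return a modified [TetradExperiment-class].
#' @export
applyConversionAndViability <- function(x, config) {
  stopifnot(is(x, "TetradExperiment"), is(config, "SimulationConfig"))
  calls <- alleleCalls(x)
  cd <- sporeInfo(x)
  nt <- nTetrads(x)
  M <- nrow(calls)
  cr <- config@conversion_rate
  if (cr > 0 && M > 0 && nt > 0) {
    hits <- which(matrix(stats::runif(M * nt) < cr, M, nt),
                  arr.ind = TRUE)
    if (nrow(hits)) {
      cls <- sample(names(config@conversion_mix), nrow(hits),
                    replace = TRUE, prob = config@conversion_mix)
      for (h in seq_len(nrow(hits))) {
        mi <- hits[h, 1L]
        cols <- (hits[h, 2L] - 1L) * 4L + 1:4
        v <- calls[mi, cols]
        if (anyNA(v)) next
        v <- switch(cls[h],
          "3:1" = { j <- which(v == "P2")
                    if (length(j)) v[sample(rep(j, 2L), 1L)] <- "P1"
                    v },
          "1:3" = { j <- which(v == "P1")
                    if (length(j)) v[sample(rep(j, 2L), 1L)] <- "P2"
                    v },
          "4:0" = rep("P1", 4L),
          "0:4" = rep("P2", 4L))
        calls[mi, cols] <- v
      }
    }
  }
  viable <- cd$viable
  if (config@spore_viability < 1) {
    dead <- stats::runif(length(viable)) > config@spore_viability
    viable <- viable & !dead
    calls[, !viable] <- NA_character_
  }
  TetradExperiment(calls, markerInfo(x), tetrad_id = cd$tetrad_id,
                   spore_id = cd$spore_id, viable = viable,
                   strain = strainLabel(x))
}

#' Simulate a tetrad dataset
#'
#' Runs the full generative model of [SimulationConfig-class]: draws
#' crossovers per bivalent under the gamma-renewal interference model,
#' resolves them into four chromatids (uniform, independent chromatid
#' choice), deals chromatids to spores with independent assortment
#' across chromosomes, then overlays gene conversion and spore death.
#' Deterministic for a fixed seed.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides \code{config@seed} when given.
#' @param strain strain label for the dataset.
#' @return a [TetradExperiment-class] of \code{config@n_tetrads}
#'   tetrads (\code{t0001 ...}, spores \code{a}-\code{d}).
#' @export
#' @examples
#' cfg <- SimulationConfig(
#'   data.frame(marker = c("L", "R"), chromosome = "I",
#'              order_index = 1:2),
#'   lengths_cM = 20, n_tetrads = 200, seed = 7)
#' tallyIntervals(simulateTetrads(cfg))
simulateTetrads <- function(config, seed = NULL,
                            strain = "simulated") {
  stopifnot(is(config, "SimulationConfig"))
  seed <- seed %||% config@seed
  if (!is.na(seed)) set.seed(seed)
  mk <- config@markers
  n <- config@n_tetrads
  calls <- NULL
  for (ch in unique(mk$chromosome)) {
    sel <- mk$chromosome == ch
    pos_M <- mk$position_M[sel] - min(mk$position_M[sel])
    L <- max(pos_M)
    xo <- drawCrossovers(L, config@interference_m, n, config@origin)
    counts <- lengths(xo)
    Ktot <- sum(counts)
    pick1 <- sample.int(2L, Ktot, replace = TRUE)
    pick2 <- sample.int(2L, Ktot, replace = TRUE) + 2L
    # product content per tetrad: 4n x M logical, TRUE = P1, built by
    # the same strand-path construction as .chromatidAlleles
    B <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), times = n),
                nrow = 4L * n, ncol = length(pos_M))
    ptr <- 0L
    for (i in which(counts > 0L)) {
      rows <- (i - 1L) * 4L
      A <- .chromatidAlleles(
        xo[[i]],
        cbind(pick1[ptr + seq_len(counts[i])],
              pick2[ptr + seq_len(counts[i])]),
        pos_M)
      ptr <- ptr + counts[i]
      B[rows + 1:4, ] <- A
    }
    # independent assortment: permute the four chromatids per tetrad
    perm <- apply(matrix(stats::runif(4L * n), 4L, n), 2L, order)
    src <- as.vector(perm) + rep((seq_len(n) - 1L) * 4L, each = 4L)
    B <- B[src, , drop = FALSE]
    cc <- matrix(ifelse(t(B), "P1", "P2"), nrow = sum(sel),
                 dimnames = list(mk$marker[sel], NULL))
    calls <- rbind(calls, cc)
  }
  te <- TetradExperiment(calls, mk, strain = strain)
  applyConversionAndViability(te, config)
}
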