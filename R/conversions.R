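#' Detect gene-conversion (non-Mendelian segregation) events
#'
#' Computes per-locus segregation (count of P1 vs P2 calls among the
#' four spores) for each tetrad and reports loci that deviate from 2:2,
#' classified as \code{3:1}, \code{1:3}, \code{4:0} or \code{0:4}.
#' Runs of adjacent loci (consecutive \code{order_index} on the same
#' chromosome) that all segregate non-2:2 are merged into a single
#' conversion event, since a single heteroduplex tract can span several
#' nearby markers.  Adjacency is positional rank, not physical distance.
#'
#' All spores of the processed tetrads must be viable; loci with a
#' missing call in a tetrad are skipped for that tetrad.
#'
#' @param x a [TetradExperiment-class].
#' @param tetrads tetrad ids to process (default: all).  An inviable
#'   spore among them is an error -- filter first, e.g. with
#'   [filterForConversionAnalysis()].
#' @return data.frame with one row per merged event: \code{tetrad_id},
#'   \code{chromosome}, \code{markers} (comma-separated loci in the
#'   run), \code{classes} (their per-locus segregation classes) and
#'   \code{n_loci}.
#' @export
detectConversions <- function(x, tetrads = tetradNames(x)) {
  stopifnot(is(x, "TetradExperiment"))
  x <- selectTetrads(x, tetrads)
  cd <- sporeInfo(x)
  if (!all(cd$viable))
    stop("detectConversions requires 4-spore-viable tetrads; ",
         "filter inviable tetrads first")
  mm <- markerInfo(x)
  mm <- mm[order(match(mm$chromosome, unique(mm$chromosome)),
                 mm$order_index), , drop = FALSE]
  calls <- alleleCalls(x)[mm$marker, , drop = FALSE]
  tid <- cd$tetrad_id
  tets <- unique(tid)
  out <- vector("list", length(tets))
  for (i in seq_along(tets)) {
    cc <- calls[, tid == tets[i], drop = FALSE]
    nP1 <- rowSums(cc == "P1")
    nP1[rowSums(is.na(cc)) > 0L] <- 2L   # missing call: treat as 2:2
    cls <- c("0:4", "1:3", "2:2", "3:1", "4:0")[nP1 + 1L]
    non <- nP1 != 2L
    if (!any(non)) next
    # maximal runs of adjacent non-2:2 loci within a chromosome
    M <- nrow(mm)
    brk <- c(TRUE, diff(mm$order_index) != 1L |
               mm$chromosome[-1L] != mm$chromosome[-M])
    newrun <- non & (brk | c(FALSE, !non[-M]))
    ev <- split(which(non), cumsum(newrun)[non])
    out[[i]] <- data.frame(
      tetrad_id = tets[i],
      chromosome = vapply(ev, function(k) mm$chromosome[k[1L]], ""),
      markers = vapply(ev, function(k)
        paste(mm$marker[k], collapse = ","), ""),
      classes = vapply(ev, function(k)
        paste(cls[k], collapse = ","), ""),
      n_loci = lengths(ev),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(tetrad_id = character(), chromosome = character(),
                      markers = character(), classes = character(),
                      n_loci = integer())
  rownames(out) <- NULL
  out
}

#' Filter tetrads for gene-conversion analysis
#'
#' Retains tetrads with four viable spores and at most
#' \code{max_events} merged conversion events (see
#' [detectConversions()]).  This is the standard filter applied before
#' tallying non-Mendelian segregation, removing tetrads whose aberrant
#' segregation more likely reflects dissection or genotyping error than
#' recombination.
#'
#' @param x a [TetradExperiment-class].
#' @param max_events maximum merged conversion events per tetrad
#'   (default 2).
#' @return a filtered [TetradExperiment-class].
#' @export
filterForConversionAnalysis <- function(x, max_events = 2L) {
  stopifnot(is(x, "TetradExperiment"))
  cd <- sporeInfo(x)
  viable4 <- vapply(split(cd$viable, cd$tetrad_id), all, logical(1))
  keep <- names(viable4)[viable4]
  keep <- keep[order(match(keep, tetradNames(x)))]
  if (!length(keep))
    return(selectTetrads(x, character(0)))
  y <- selectTetrads(x, keep)
  ev <- detectConversions(y)
  nev <- table(factor(ev$tetrad_id, levels = keep))
  selectTetrads(y, keep[nev <= max_events])
}
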