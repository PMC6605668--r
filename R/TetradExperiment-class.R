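#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' TetradExperiment: genotyped four-spore tetrads
#'
#' A container for allele calls from dissected meiotic tetrads, built on
#' \linkS4class{SummarizedExperiment}.  Rows are genetic markers, columns
#' are individual spores.  The single assay, \code{"calls"}, is a
#' character matrix with entries \code{"P1"}, \code{"P2"} (the two
#' parental alleles) or \code{NA} (missing / inviable).
#'
#' Row metadata declares the marker map: \code{chromosome},
#' \code{order_index} (position rank along the chromosome) and
#' \code{phase} (which raw allele label belonged to parent 1; purely
#' bookkeeping, since calls are already expressed as P1/P2).  Column
#' metadata carries \code{tetrad_id}, \code{spore_id} and \code{viable};
#' every tetrad has exactly four spore columns and inviable spores have
#' all calls missing.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [TetradExperiment()] the constructor, [readTetradTable()],
#'   [classifyTetrads()], [simulateTetrads()]
#' @export
setClass("TetradExperiment", contains = "SummarizedExperiment")

.validTetradExperiment <- function(object) {
  msg <- NULL
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  calls <- assay(object, "calls")
  if (!is.character(calls))
    msg <- c(msg, "'calls' must be a character matrix")
  else if (!all(calls %in% c("P1", "P2", NA_character_)))
    msg <- c(msg, "allele calls must be 'P1', 'P2' or NA")
  rd <- rowData(object)
  need <- c("chromosome", "order_index")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData needs columns 'chromosome' and 'order_index'")
  else {
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "marker names must be unique")
    for (ch in unique(rd$chromosome)) {
      oi <- rd$order_index[rd$chromosome == ch]
      if (anyDuplicated(oi))
        msg <- c(msg, sprintf(
          "order_index must be unique within chromosome '%s'", ch))
    }
  }
  cd <- colData(object)
  need <- c("tetrad_id", "spore_id", "viable")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, "colData needs 'tetrad_id', 'spore_id' and 'viable'")
  } else {
    sizes <- table(cd$tetrad_id)
    if (length(sizes) && any(sizes != 4L))
      msg <- c(msg, sprintf(
        "every tetrad needs exactly 4 spores; offending tetrad(s): %s",
        paste(names(sizes)[sizes != 4L], collapse = ", ")))
    if (anyDuplicated(paste(cd$tetrad_id, cd$spore_id, sep = "\r")))
      msg <- c(msg, "spore ids must be unique within a tetrad")
    if (is.character(calls) && any(!cd$viable &
        colSums(!is.na(calls)) > 0L))
      msg <- c(msg, "inviable spores must have all calls missing")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("TetradExperiment", .validTetradExperiment)

#' Construct a TetradExperiment
#'
#' @param calls character matrix (markers x spores) of \code{"P1"},
#'   \code{"P2"} or \code{NA} calls.  Row names are marker names; columns
#'   are ordered spore-within-tetrad.
#' @param markers data.frame describing the marker map with columns
#'   \code{marker}, \code{chromosome}, \code{order_index} and optionally
#'   \code{phase}.  Markers absent from \code{calls} rows are dropped;
#'   rows of \code{calls} are reordered to map order.
#' @param tetrad_id,spore_id,viable per-spore column metadata.  If
#'   \code{tetrad_id} is missing, consecutive groups of four columns are
#'   taken as tetrads \code{t0001, t0002, ...} with spores
#'   \code{a, b, c, d}.
#' @param strain optional strain label stored in \code{metadata()}.
#' @return a [TetradExperiment-class] object.
#' @export
#' @examples
#' mk <- data.frame(marker = c("HIS4", "CEN3"), chromosome = "III",
#'                  order_index = 1:2)
#' calls <- matrix(c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P2"),
#'                 nrow = 2, dimnames = list(mk$marker, NULL))
#' te <- TetradExperiment(calls, mk, strain = "demo")
#' nTetrads(te)
TetradExperiment <- function(calls, markers, tetrad_id = NULL,
                             spore_id = NULL, viable = NULL,
                             strain = NA_character_) {
  if (is.null(rownames(calls)))
    stop("'calls' must have marker row names")
  markers <- .normalizeMarkerMap(markers)
  unknown <- setdiff(rownames(calls), markers$marker)
  if (length(unknown))
    stop("calls reference undeclared marker(s): ",
         paste(unknown, collapse = ", "))
  markers <- markers[markers$marker %in% rownames(calls), , drop = FALSE]
  calls <- calls[markers$marker, , drop = FALSE]
  ns <- ncol(calls)
  if (is.null(tetrad_id)) {
    if (ns %% 4L != 0L)
      stop("number of spore columns must be a multiple of 4")
    tetrad_id <- rep(sprintf("t%04d", seq_len(ns / 4L)), each = 4L)
    spore_id <- rep(c("a", "b", "c", "d"), ns / 4L)
  }
  if (is.null(spore_id))
    stop("'spore_id' must accompany 'tetrad_id'")
  if (is.null(viable))
    viable <- colSums(!is.na(calls)) > 0L | nrow(calls) == 0L
  cd <- DataFrame(tetrad_id = as.character(tetrad_id),
                  spore_id = as.character(spore_id),
                  viable = as.logical(viable))
  rownames(cd) <- paste(tetrad_id, spore_id, sep = ":")
  colnames(calls) <- rownames(cd)
  rd <- DataFrame(chromosome = markers$chromosome,
                  order_index = markers$order_index,
                  phase = markers$phase,
                  row.names = markers$marker)
  se <- SummarizedExperiment(assays = list(calls = calls),
                             rowData = rd, colData = cd)
  metadata(se)$strain <- strain
  new("TetradExperiment", se)
}

.normalizeMarkerMap <- function(markers) {
  if (!is.data.frame(markers))
    stop("'markers' must be a data.frame")
  need <- c("marker", "chromosome", "order_index")
  if (!all(need %in% colnames(markers)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(markers$marker))
    stop("marker names must be unique")
  if (is.null(markers$phase)) markers$phase <- "P1"
  markers$order_index <- as.integer(markers$order_index)
  markers <- markers[order(markers$chromosome, markers$order_index), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  markers
}

#' Accessors for TetradExperiment
#'
#' \code{alleleCalls} returns the markers x spores call matrix;
#' \code{markerInfo} the marker map (as a data.frame); \code{sporeInfo}
#' the per-spore metadata; \code{tetradNames} the tetrad identifiers;
#' \code{nTetrads} their number; \code{strainLabel} the strain label.
#'
#' @param x a [TetradExperiment-class].
#' @return see individual descriptions.
#' @name tetrad-accessors
#' @aliases alleleCalls markerInfo sporeInfo tetradNames nTetrads
#'   strainLabel
NULL

#' @rdname tetrad-accessors
#' @export
setGeneric("alleleCalls", function(x) standardGeneric("alleleCalls"))
#' @rdname tetrad-accessors
#' @export
setMethod("alleleCalls", "TetradExperiment",
          function(x) assay(x, "calls"))

#' @rdname tetrad-accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname tetrad-accessors
#' @export
setMethod("markerInfo", "TetradExperiment", function(x) {
  rd <- rowData(x)
  data.frame(marker = rownames(x), chromosome = rd$chromosome,
             order_index = rd$order_index, phase = rd$phase,
             row.names = NULL)
})

#' @rdname tetrad-accessors
#' @export
setGeneric("sporeInfo", function(x) standardGeneric("sporeInfo"))
#' @rdname tetrad-accessors
#' @export
setMethod("sporeInfo", "TetradExperiment",
          function(x) as.data.frame(colData(x)))

#' @rdname tetrad-accessors
#' @export
setGeneric("tetradNames", function(x) standardGeneric("tetradNames"))
#' @rdname tetrad-accessors
#' @export
setMethod("tetradNames", "TetradExperiment",
          function(x) unique(colData(x)$tetrad_id))

#' @rdname tetrad-accessors
#' @export
setGeneric("nTetrads", function(x) standardGeneric("nTetrads"))
#' @rdname tetrad-accessors
#' @export
setMethod("nTetrads", "TetradExperiment",
          function(x) length(tetradNames(x)))

#' @rdname tetrad-accessors
#' @export
setGeneric("strainLabel", function(x) standardGeneric("strainLabel"))
#' @rdname tetrad-accessors
#' @export
setMethod("strainLabel", "TetradExperiment", function(x) {
  s <- metadata(x)$strain
  if (is.null(s)) NA_character_ else s
})

#' Subset a TetradExperiment to whole tetrads
#'
#' Keeps all four spores of each selected tetrad, preserving validity.
#'
#' @param x a [TetradExperiment-class].
#' @param tetrads character vector of tetrad identifiers to keep.
#' @return a [TetradExperiment-class] with the selected tetrads.
#' @export
selectTetrads <- function(x, tetrads) {
  stopifnot(is(x, "TetradExperiment"))
  miss <- setdiff(tetrads, tetradNames(x))
  if (length(miss))
    stop("unknown tetrad id(s): ", paste(miss, collapse = ", "))
  keep <- colData(x)$tetrad_id %in% tetrads
  x[, keep]
}

setMethod("show", "TetradExperiment", function(object) {
  cat(sprintf(
    "TetradExperiment: %d tetrad(s) x %d marker(s) on %d chromosome(s)\n",
    nTetrads(object), nrow(object),
    length(unique(rowData(object)$chromosome))))
  s <- strainLabel(object)
  if (!is.na(s)) cat("strain:", s, "\n")
  v <- colData(object)$viable
  cat(sprintf("spores: %d (%d viable, %.1f%%)\n", length(v), sum(v),
              if (length(v)) 100 * mean(v) else NA_real_))
  cat("markers:", paste(utils::head(rownames(object), 9),
                        collapse = ", "),
      if (nrow(object) > 9) "..." else "", "\n")
})
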