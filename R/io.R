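#' Read a marker map
#'
#' Tab-separated file with header
#' \code{marker<TAB>chromosome<TAB>order_index<TAB>phase}; one row per
#' marker.  \code{order_index} orders markers along their chromosome and
#' \code{phase} records which raw allele label belonged to parent 1
#' (bookkeeping only -- tetrad tables carry calls already mapped to
#' P1/P2).
#'
#' @param path file path.
#' @return data.frame with columns \code{marker}, \code{chromosome},
#'   \code{order_index}, \code{phase}.
#' @export
readMarkerMap <- function(path) {
  mm <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  .normalizeMarkerMap(mm)
}

#' Read a tetrad genotype table
#'
#' The tetrad TSV dialect has header
#' \code{tetrad_id<TAB>spore_id<TAB>viable<TAB><marker1><TAB>...}, one
#' row per spore, \code{viable} in \{1, 0\} and calls in
#' \{\code{P1}, \code{P2}, \code{-}\} (\code{-} = missing).  Every
#' tetrad must have exactly four spore rows.
#'
#' @param path file path.
#' @param markers marker map data.frame (see [readMarkerMap()]); marker
#'   columns in the file must be declared here.
#' @param strain optional strain label.
#' @return a [TetradExperiment-class].
#' @export
readTetradTable <- function(path, markers, strain = NA_character_) {
  markers <- .normalizeMarkerMap(markers)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = "character")
  need <- c("tetrad_id", "spore_id", "viable")
  if (!all(need %in% colnames(df)))
    stop("tetrad table needs columns: ", paste(need, collapse = ", "))
  mcols <- setdiff(colnames(df), need)
  unknown <- setdiff(mcols, markers$marker)
  if (length(unknown))
    stop("tetrad table has undeclared marker column(s): ",
         paste(unknown, collapse = ", "))
  sizes <- table(df$tetrad_id)
  if (any(sizes != 4L))
    stop("tetrad(s) without exactly 4 spore rows: ",
         paste(names(sizes)[sizes != 4L], collapse = ", "))
  bad <- !df$viable %in% c("0", "1")
  if (any(bad))
    stop("'viable' must be 0 or 1 (tetrad ",
         df$tetrad_id[which(bad)[1]], ")")
  callsok <- vapply(mcols, function(m)
    all(df[[m]] %in% c("P1", "P2", "-")), logical(1))
  if (!all(callsok))
    stop("calls must be 'P1', 'P2' or '-' (marker ",
         mcols[which(!callsok)[1]], ")")
  calls <- t(as.matrix(df[, mcols, drop = FALSE]))
  calls[calls == "-"] <- NA_character_
  viable <- df$viable == "1"
  calls[, !viable] <- NA_character_
  TetradExperiment(calls, markers, tetrad_id = df$tetrad_id,
                   spore_id = df$spore_id, viable = viable,
                   strain = strain)
}

#' Write a tetrad genotype table
#'
#' Inverse of [readTetradTable()]: emits the tetrad TSV dialect with
#' missing calls written as \code{-}.
#'
#' @param x a [TetradExperiment-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTetradTable <- function(x, path) {
  stopifnot(is(x, "TetradExperiment"))
  cd <- sporeInfo(x)
  calls <- t(alleleCalls(x))
  calls[is.na(calls)] <- "-"
  df <- data.frame(tetrad_id = cd$tetrad_id, spore_id = cd$spore_id,
                   viable = as.integer(cd$viable),
                   calls, check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a marker map
#'
#' @param markers marker map data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMarkerMap <- function(markers, path) {
  markers <- .normalizeMarkerMap(markers)
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reference crossover count tables
#'
#' Published per-interval tetrad classification counts (PD/TT/NPD) and
#' random-spore recombinant counts for a panel of Saccharomyces
#' cerevisiae zip1, msh4 and pch2 mutant strains genotyped at five loci
#' on chromosome III (HIS4, CEN3, MAT, RAD18, HMR) and four on
#' chromosome VIII (SPO11, SPO13, THR1, LYS2), together with the map
#' statistics the source tables display (cM, SE, percent of control,
#' per-chromosome sums, NPD obs/exp ratios).  The displayed statistics
#' are retained so recomputed values can be checked against them; a few
#' cells of the source tables are internally inconsistent (see the
#' package vignette) and are kept verbatim.
#'
#' @return data.frame; one row per strain x interval.
#' @export
#' @examples
#' counts <- referenceCrossoverCounts()
#' head(counts)
referenceCrossoverCounts <- function() {
  utils::read.delim(system.file("extdata", "zip1_tetrad_counts.tsv",
                                package = "tetramap"),
                    stringsAsFactors = FALSE)
}

#' @rdname referenceCrossoverCounts
#' @export
referenceRandomSporeCounts <- function() {
  utils::read.delim(system.file("extdata", "zip1_random_spore_counts.tsv",
                                package = "tetramap"),
                    stringsAsFactors = FALSE)
}

#' Marker map of the reference cross
#'
#' The nine-locus map used by [referenceCrossoverCounts()]: five loci
#' spanning chromosome III and four spanning a segment of chromosome
#' VIII, defining seven genetic intervals.
#'
#' @return marker map data.frame (see [readMarkerMap()]).
#' @export
referenceMarkerMap <- function() {
  data.frame(
    marker = c("HIS4", "CEN3", "MAT", "RAD18", "HMR",
               "SPO11", "SPO13", "THR1", "LYS2"),
    chromosome = rep(c("III", "VIII"), c(5L, 4L)),
    order_index = c(1:5, 1:4),
    phase = "P1",
    stringsAsFactors = FALSE)
}
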