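#' @title Generics for kmerdepth classes
#' @description Accessor generics used across the package's S4 classes.
#' @param x an object of a kmerdepth class.
#' @param ... further arguments passed to methods.
#' @return See the individual methods.
#' @name kmerdepth-generics
#' @keywords internal
NULL

#' @describeIn kmerdepth-generics k-mer length (bases) of the object.
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @describeIn kmerdepth-generics tag k-mer table (`data.frame` with columns
#'   `kmer`, `record`, `position`, `window_1mb`).
#' @export
setGeneric("tagKmers", function(x) standardGeneric("tagKmers"))

#' @describeIn kmerdepth-generics error k-mer table (`data.frame` with columns
#'   `kmer`, `parent`, `mm_pos`, `mm_base`).
#' @export
setGeneric("errorKmers", function(x) standardGeneric("errorKmers"))

#' @describeIn kmerdepth-generics provenance metadata (`list`).
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn kmerdepth-generics occurrence counts of canonical k-mers.
#' @param kmers character vector of k-mer strings to look up.
#' @export
setGeneric("kmerCount", function(x, kmers) standardGeneric("kmerCount"))

#' @describeIn kmerdepth-generics named per-tag observed counts.
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @describeIn kmerdepth-generics named per-error-k-mer observed counts.
#' @export
setGeneric("errorCounts", function(x) standardGeneric("errorCounts"))

#' @describeIn kmerdepth-generics total number of nucleotides consumed
#'   (including N and other non-ACGT bases).
#' @export
setGeneric("nNucl", function(x) standardGeneric("nNucl"))

#' @describeIn kmerdepth-generics total number of ACGT-only k-length windows.
#' @export
setGeneric("nKmer", function(x) standardGeneric("nKmer"))

#' @describeIn kmerdepth-generics number of reads consumed.
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @describeIn kmerdepth-generics estimated depth of coverage.
#' @export
setGeneric("depthOfCoverage", function(x) standardGeneric("depthOfCoverage"))

#' @describeIn kmerdepth-generics estimated per-nucleotide substitution error
#'   rate.
#' @export
setGeneric("errorRate", function(x) standardGeneric("errorRate"))
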