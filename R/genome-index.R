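#' Index the canonical k-mers of a genome assembly
#'
#' Builds the occurrence index used by every list-building filter: each
#' canonical k-mer of the assembly is mapped to its count over all records
#' (each genomic window counted once; strands collapsed by canonical form) and
#' to the record/position of its first occurrence, which for count-1 k-mers is
#' the unique locus carried through to the tag list.
#'
#' @param x FASTA path(s) (plain or gzipped, multi-record, soft-masking
#'   allowed), an `XStringSet`, or a named character vector of sequences.
#' @param k integer k-mer length (default 25).
#' @return a [GenomeKmerIndex-class] object.
#' @examples
#' idx <- buildGenomeIndex(c(chr1 = "ACGTACGT"), k = 5)
#' kmerCount(idx, c("ACGTA", "CGTAC"))
#' @export
buildGenomeIndex <- function(x, k = 25) {
  k <- as.integer(k)
  seqs <- .asSequences(x, "genome FASTA")
  ptr <- cpp_build_index(unname(seqs), names(seqs), k)
  st <- cpp_index_stats(ptr)
  rl <- st$record_lengths
  names(rl) <- st$record_names
  new("GenomeKmerIndex", ptr = ptr, k = k, recordLengths = rl,
      nDistinct = st$n_distinct, nWindows = st$n_windows,
      source = .sourceLabel(x))
}

#' @rdname buildGenomeIndex
#' @param object,x a `GenomeKmerIndex`.
#' @param kmers character vector of k-mers to look up (either orientation).
#' @export
setMethod("kmerCount", "GenomeKmerIndex", function(x, kmers) {
  out <- cpp_index_count(x@ptr, as.character(kmers))
  names(out) <- kmers
  out
})

#' @rdname buildGenomeIndex
#' @export
setMethod("kmerLength", "GenomeKmerIndex", function(x) x@k)

#' @rdname buildGenomeIndex
#' @export
recordLengths <- function(x) {
  stopifnot(is(x, "GenomeKmerIndex"))
  x@recordLengths
}

setMethod("show", "GenomeKmerIndex", function(object) {
  cat("GenomeKmerIndex (k = ", object@k, ")\n", sep = "")
  cat("  records:          ", length(object@recordLengths),
      " (", format(sum(object@recordLengths), big.mark = ","), " bp)\n", sep = "")
  cat("  windows indexed:  ", format(object@nWindows, big.mark = ","), "\n", sep = "")
  cat("  distinct k-mers:  ", format(object@nDistinct, big.mark = ","), "\n", sep = "")
  cat("  source:           ", object@source, "\n", sep = "")
})

#' @export
#' @method as.data.frame GenomeKmerIndex
#' @rdname buildGenomeIndex
#' @param row.names,optional,... ignored (S3 compatibility).
as.data.frame.GenomeKmerIndex <- function(x, row.names = NULL, optional = FALSE, ...) {
  cpp_index_dump(x@ptr)
}

setMethod("show", "KmerCandidateSet", function(object) {
  cat("KmerCandidateSet (k = ", object@k, "): ",
      format(object@n, big.mark = ","), " candidate loci\n", sep = "")
})

#' @export
#' @method as.data.frame KmerCandidateSet
#' @rdname selectUniqueUniversal
#' @param row.names,optional,... ignored (S3 compatibility).
as.data.frame.KmerCandidateSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  cpp_cand_df(x@ptr)
}

#' @export
setMethod("length", "KmerCandidateSet", function(x) as.integer(x@n))
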