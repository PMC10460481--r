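#' Canonical form of k-mer strings
#'
#' The canonical form of a k-mer is the lexicographically smaller (under
#' `A < C < G < T`) of the word and its reverse complement. All k-mer
#' identity in this package -- list building, counting, neighbor tests -- is
#' canonical, which makes counting strand-independent (reads originate from
#' both strands). Lowercase (soft-masked) input is case-folded; any other
#' character is an error.
#'
#' @param x character vector of k-mer strings (each of length 1--32 bases,
#'   ACGT/acgt only).
#' @return character vector of canonical k-mer strings (uppercase).
#' @examples
#' canonicalKmer(c("TTTTT", "AAAAA"))  # both "AAAAA"
#' @export
canonicalKmer <- function(x) {
  cpp_canonical(as.character(x))
}

#' Pack / unpack k-mers as 2-bit codes
#'
#' `encodeKmer()` returns the canonical k-mer packed at 2 bits per base
#' (`A=0, C=1, G=2, T=3`, leftmost base most significant) as a double;
#' exact only for `k <= 26` (codes below 2^52). `decodeKmer()` is the
#' inverse. Internally the package works on 64-bit words for any
#' `k <= 32`; these R-level views exist for inspection and testing.
#'
#' @param x character vector of k-mer strings.
#' @param code numeric vector of packed codes.
#' @param k integer k-mer length.
#' @return `encodeKmer()`: numeric codes; `decodeKmer()`: character k-mers.
#' @examples
#' encodeKmer("ACGT")            # canonical("ACGT") = "ACGT" -> 27
#' decodeKmer(27, 4)
#' @export
encodeKmer <- function(x) {
  x <- as.character(x)
  if (any(nchar(x) > 26))
    stop("encodeKmer() is exact only for k <= 26; longer k-mers are handled ",
         "internally but have no lossless double representation")
  cpp_encode(x)
}

#' @rdname encodeKmer
#' @export
decodeKmer <- function(code, k) {
  if (k > 26) stop("decodeKmer() supports k <= 26")
  cpp_decode(as.numeric(code), as.integer(k))
}

#' Hamming distance between equal-length k-mers
#'
#' Number of positions at which two words differ, computed on the strings as
#' given (no canonicalization); this is the metric of the isolation filter
#' that removes tag candidates with another genomic k-mer within distance 1.
#'
#' @param a,b character vectors of equal-length k-mer strings (recycled to a
#'   common length).
#' @return integer vector of distances in `0..k`.
#' @examples
#' hammingDistance("AAAAA", "AAAAT")  # 1
#' @export
hammingDistance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  cpp_hamming(rep_len(a, n), rep_len(b, n))
}

#' Single-mismatch neighborhood of a k-mer
#'
#' Enumerates the 3k words at Hamming distance 1 from the canonical form of
#' `x` and returns their canonical forms (sorted, deduplicated). A neighbor
#' whose canonical form collapses onto `x`'s own canonical form (a
#' near-palindromic word reachable from its reverse complement by one
#' substitution) is dropped: it is the same k-mer family under canonical
#' counting. This set implements the distance-1 membership test behind the
#' isolation filter without any all-pairs comparison.
#'
#' @param x a single k-mer string.
#' @return character vector of canonical neighbor k-mers (at most 3k).
#' @examples
#' mismatchNeighbors("AA")  # canonical forms of {CA,GA,TA,AC,AG,AT}
#' @export
mismatchNeighbors <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  cpp_neighbors(x)
}

#' Scan a sequence into canonical k-mer windows
#'
#' Slides a k-length window over `seq`, emitting one canonical k-mer per
#' ACGT-only window in left-to-right order. Windows overlapping any non-ACGT
#' character (N, IUPAC codes) are skipped, but every character still counts
#' toward `n_nucl`; near such characters and at read ends there are therefore
#' fewer k-mers than nucleotides, which is exactly the deficit the depth
#' estimator corrects with the `n_nucl / n_kmer` ratio.
#'
#' @param seq a single sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`).
#' @param k integer k-mer length (1--32).
#' @return a list with elements `position` (0-based window starts), `kmer`
#'   (canonical strings), `n_nucl` and `n_kmer`.
#' @examples
#' scanSequence("ACGTNACGT", 4)
#' @export
scanSequence <- function(seq, k) {
  seq <- .asSequences(seq, "seq")
  if (length(seq) != 1L) stop("seq must be a single sequence")
  cpp_scan(unname(seq), as.integer(k))
}
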