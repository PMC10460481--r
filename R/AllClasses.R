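## Central S4 classes. Positions are 0-based throughout (leftmost base of the
## k-mer on the forward strand of the source record); k-mer strings are always
## stored in canonical orientation (lexicographically smaller of word and
## reverse complement under A<C<G<T).

#' GenomeKmerIndex: canonical k-mer occurrence index of a genome assembly
#'
#' Maps every canonical k-mer of an assembly to its occurrence count (each
#' genomic window counted once, strands collapsed) and, for k-mers seen once,
#' to the record and 0-based position of that unique locus. The index is held
#' in native memory behind an external pointer, so it is cheap to query but is
#' not serializable: rebuild it with [buildGenomeIndex()] rather than saving
#' it.
#'
#' @slot ptr external pointer to the native hash map.
#' @slot k integer k-mer length (1--32).
#' @slot recordLengths named numeric vector of record lengths.
#' @slot nDistinct number of distinct canonical k-mers.
#' @slot nWindows total number of ACGT-only windows indexed (sum of counts).
#' @slot source character label of the input (file name or object note).
#' @export
setClass("GenomeKmerIndex",
  slots = c(ptr = "externalptr", k = "integer", recordLengths = "numeric",
            nDistinct = "numeric", nWindows = "numeric", source = "character"))

setValidity("GenomeKmerIndex", function(object) {
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L || object@k > 32L)
    return("k must be a single integer in 1..32")
  TRUE
})

#' KmerCandidateSet: packed candidate tag k-mer loci
#'
#' Intermediate result of the list-building filters: a set of (k-mer, record,
#' position) triples kept in packed native memory so that genome-scale
#' candidate sets (tens of millions) never materialize as R strings. Use
#' `as.data.frame()` to inspect small sets.
#'
#' @slot ptr external pointer to the packed candidate arrays.
#' @slot k integer k-mer length.
#' @slot n number of candidates.
#' @export
setClass("KmerCandidateSet",
  slots = c(ptr = "externalptr", k = "integer", n = "numeric"))

#' KmerDatabase: tag and error k-mer lists
#'
#' The counting database: tag k-mers (unique in every filtered assembly,
#' Hamming-isolated, window-spaced) with their genomic annotation, and error
#' k-mers (single-mismatch variants of tags, absent from the genome). List
#' sizes are the denominators of the per-k-mer mean depths used by
#' [runEstimation()].
#'
#' @slot k integer k-mer length.
#' @slot tags `data.frame` with columns `kmer`, `record`, `position` (0-based),
#'   `window_1mb` (`floor(position / 1e6)`).
#' @slot errors `data.frame` with columns `kmer`, `parent` (tag k-mer string),
#'   `mm_pos` (0-based mismatch position within the parent's canonical
#'   orientation), `mm_base` (substituted base).
#' @slot provenance list of free-form metadata (source genomes, filter
#'   parameters, seed).
#' @slot cache environment holding the native lookup table (never serialized;
#'   rebuilt on demand).
#' @export
setClass("KmerDatabase",
  slots = c(k = "integer", tags = "data.frame", errors = "data.frame",
            provenance = "list", cache = "environment"))

setValidity("KmerDatabase", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L || k > 32L)
    return("k must be a single integer in 1..32")
  tg <- object@tags
  er <- object@errors
  need_t <- c("kmer", "record", "position", "window_1mb")
  need_e <- c("kmer", "parent", "mm_pos", "mm_base")
  if (!all(need_t %in% names(tg)))
    return("tags must have columns kmer, record, position, window_1mb")
  if (!all(need_e %in% names(er)))
    return("errors must have columns kmer, parent, mm_pos, mm_base")
  if (nrow(tg) > 0 && any(nchar(tg$kmer) != k))
    return("tag k-mer strings must all have length k")
  if (nrow(er) > 0 && any(nchar(er$kmer) != k))
    return("error k-mer strings must all have length k")
  if (anyDuplicated(tg$kmer)) return("duplicated tag k-mer codes")
  if (anyDuplicated(er$kmer)) return("duplicated error k-mer codes")
  if (nrow(er) > 0 && any(er$kmer %in% tg$kmer))
    return("tag and error k-mer sets must be disjoint")
  if (nrow(er) > 0 && !all(er$parent %in% tg$kmer))
    return("every error k-mer parent must be a tag k-mer")
  if (nrow(tg) > 0 && any(tg$window_1mb != tg$position %/% 1000000L))
    return("window_1mb must equal floor(position / 1e6)")
  if (nrow(er) > 0) {
    if (any(er$mm_pos < 0L | er$mm_pos >= k))
      return("mm_pos must be in 0..k-1")
    recon <- er$parent
    substr(recon, er$mm_pos + 1L, er$mm_pos + 1L) <- er$mm_base
    if (any(recon == er$parent))
      return("mm_base must differ from the parent base at mm_pos")
    if (!all(cpp_canonical(recon) == er$kmer))
      return("error k-mer is not the canonical single-mismatch variant of its parent")
  }
  # spacing guarantee: consecutive tags of one record at least
  # (keepEvery - 1) * windowLen apart (200 bp with the defaults)
  wl <- object@provenance$window_len
  ke <- object@provenance$keep_every
  if (is.null(wl)) wl <- 100L
  if (is.null(ke)) ke <- 3L
  minGap <- (as.integer(ke) - 1L) * as.integer(wl)
  if (minGap > 0 && nrow(tg) > 1) {
    gaps <- unlist(lapply(split(tg$position, tg$record),
                          function(p) diff(sort(p))), use.names = FALSE)
    if (length(gaps) && any(gaps < minGap))
      return(sprintf("tag spacing violated: gap %d < %d bp", min(gaps), minGap))
  }
  TRUE
})

#' KmerCounts: observed database k-mer counts plus sample tallies
#'
#' Per-k-mer observed counts of a database against one or more read files,
#' together with the sample statistics needed by the estimator: `nNucl` (all
#' bases, N included), `nKmer` (ACGT-only k-windows) and the number of reads.
#' Counts of disjoint inputs merge by field-wise addition
#' ([mergeCounts()]).
#'
#' @slot tagCounts named numeric vector, one count per tag k-mer.
#' @slot errCounts named numeric vector, one count per error k-mer.
#' @slot nNucl total nucleotides in the sample.
#' @slot nKmer total ACGT-only k-length windows in the sample.
#' @slot nReads number of reads consumed.
#' @slot sourceFiles character vector of input names.
#' @slot dbHash fingerprint of the database the counts were taken against.
#' @export
setClass("KmerCounts",
  slots = c(tagCounts = "numeric", errCounts = "numeric", nNucl = "numeric",
            nKmer = "numeric", nReads = "numeric", sourceFiles = "character",
            dbHash = "character"))

setValidity("KmerCounts", function(object) {
  if (any(object@tagCounts < 0) || any(object@errCounts < 0))
    return("counts must be non-negative")
  if (object@nKmer > object@nNucl)
    return("n_kmer cannot exceed n_nucl")
  if (sum(object@tagCounts) + sum(object@errCounts) > object@nKmer)
    return("total database hits cannot exceed the number of scanned windows")
  TRUE
})

#' DepthEstimate: depth-of-coverage and error-rate estimates
#'
#' Result of [runEstimation()]: the mean per-k-mer depths of the retained tag
#' and error lists, the error-rate and depth estimates, the Poisson-tail
#' cutoffs applied, and filtering diagnostics.
#'
#' @slot depth estimated depth of coverage `D`.
#' @slot errorRate estimated per-nucleotide substitution error rate `P_e`.
#' @slot dTag mean tag k-mer count over the retained tag list.
#' @slot dErr mean error k-mer count over the retained error list.
#' @slot cutoffTag,cutoffErr integer count cutoffs applied to the two lists.
#' @slot nTagUsed,nErrUsed retained list sizes.
#' @slot nTagRemoved,nErrRemoved k-mers eliminated by the cutoff.
#' @slot nNucl,nKmer,nReads sample tallies the estimate was computed from.
#' @slot provenance list: database provenance plus estimation parameters.
#' @export
setClass("DepthEstimate",
  slots = c(depth = "numeric", errorRate = "numeric", dTag = "numeric",
            dErr = "numeric", cutoffTag = "integer", cutoffErr = "integer",
            nTagUsed = "integer", nErrUsed = "integer",
            nTagRemoved = "integer", nErrRemoved = "integer",
            nNucl = "numeric", nKmer = "numeric", nReads = "numeric",
            provenance = "list"))

setValidity("DepthEstimate", function(object) {
  if (object@errorRate < 0 || object@errorRate > 1)
    return("error rate must lie in [0, 1]")
  if (object@depth < 0) return("depth must be non-negative")
  if (object@dTag < 0 || object@dErr < 0)
    return("mean k-mer depths must be non-negative")
  TRUE
})
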