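.newCandSet <- function(ptr) {
  info <- cpp_cand_info(ptr)
  new("KmerCandidateSet", ptr = ptr, k = as.integer(info$k), n = info$n)
}

#' Select k-mers that are unique in every assembly
#'
#' First list-building filter: a candidate tag k-mer must occur exactly once
#' in the primary assembly and exactly once in every additional assembly
#' supplied ("unique and universal"). Each candidate carries its unique locus
#' in the primary genome, which provides the coordinates used by the spacing
#' filter and the final annotation.
#'
#' @param primary a [GenomeKmerIndex-class] of the primary assembly (the
#'   coordinate and isolation reference).
#' @param others list of `GenomeKmerIndex` objects of additional assemblies;
#'   with `others = list()` the filter reduces to count-1 in the primary.
#' @return a [KmerCandidateSet-class], sorted by (record, position).
#' @seealso [filterHammingIsolated()], [filterSpacing()], [buildKmerDatabase()]
#' @export
selectUniqueUniversal <- function(primary, others = list()) {
  stopifnot(is(primary, "GenomeKmerIndex"))
  if (!is.list(others)) others <- list(others)
  for (o in others) {
    if (!is(o, "GenomeKmerIndex")) stop("others must be GenomeKmerIndex objects")
    if (o@k != primary@k)
      stop("k mismatch between genome indexes (", o@k, " vs ", primary@k, ")")
  }
  .newCandSet(cpp_select_unique(primary@ptr, lapply(others, function(o) o@ptr)))
}

#' Remove candidates with a genomic k-mer within Hamming distance 1
#'
#' Second filter: a candidate survives only if none of its 3k single-mismatch
#' neighbor words (in canonical form) occurs anywhere in the primary genome.
#' Together with uniqueness this guarantees Hamming distance >= 2 between a
#' tag and every other genomic k-mer, so that one sequencing error can never
#' convert a different genomic k-mer into a tag. Implemented by neighbor
#' enumeration against the index, never by all-pairs comparison.
#'
#' @param candidates a [KmerCandidateSet-class].
#' @param primary the [GenomeKmerIndex-class] the candidates came from.
#' @return a filtered [KmerCandidateSet-class].
#' @export
filterHammingIsolated <- function(candidates, primary) {
  stopifnot(is(candidates, "KmerCandidateSet"), is(primary, "GenomeKmerIndex"))
  .newCandSet(cpp_filter_isolated(candidates@ptr, primary@ptr))
}

#' Thin candidates to one per eligible spacing window
#'
#' Third filter: each record is partitioned into consecutive `windowLen`-bp
#' windows (indexed from 0); only windows whose index is divisible by
#' `keepEvery` may contribute, and each contributes its leftmost candidate.
#' With the defaults (100 bp windows, every third) any two tags are at least
#' 200 bp apart, so a 100 bp read can contribute to at most one tag count,
#' which caps the per-read contribution and reduces stochastic noise at low
#' depth. An eligible window with no candidates simply contributes nothing.
#'
#' @param candidates a [KmerCandidateSet-class].
#' @param windowLen window length in bp (default 100).
#' @param keepEvery keep one candidate in every `keepEvery`-th window
#'   (default 3).
#' @return `data.frame` of tag k-mers with columns `kmer`, `record`,
#'   `position` (0-based) and `window_1mb`, sorted by (record, position).
#' @export
filterSpacing <- function(candidates, windowLen = 100, keepEvery = 3) {
  stopifnot(is(candidates, "KmerCandidateSet"))
  cpp_filter_spacing(candidates@ptr, as.integer(windowLen), as.integer(keepEvery))
}

#' Generate error k-mers: single-mismatch variants of the tags
#'
#' For each tag k-mer, up to `nVariants` distinct single-substitution variants
#' are drawn uniformly without replacement from the 3k possibilities (mismatch
#' position and substituted base both random). A variant is kept only if it is
#' absent from the primary genome, no genomic k-mer other than its parent lies
#' within Hamming distance 1 of it, and it collides with no tag and no
#' previously accepted error k-mer. A tag may therefore yield fewer than
#' `nVariants` variants (recorded by the caller's provenance). Counts of these
#' absent-from-genome k-mers measure how often sequencing errors convert a tag
#' into a specific one-off variant, which is what the error-rate estimator
#' inverts.
#'
#' @param tags tag `data.frame` as returned by [filterSpacing()] (a `kmer`
#'   column is required), or a `KmerDatabase`.
#' @param primary the [GenomeKmerIndex-class] of the primary assembly.
#' @param nVariants variants attempted per tag (default 4).
#' @param seed optional integer seed for the draw; with `seed = NULL` the
#'   caller's RNG stream is used.
#' @return `data.frame` with columns `kmer`, `parent`, `mm_pos` (0-based
#'   mismatch position within the parent's canonical orientation), `mm_base`.
#' @export
generateErrorKmers <- function(tags, primary, nVariants = 4, seed = NULL) {
  if (is(tags, "KmerDatabase")) tags <- tagKmers(tags)
  stopifnot(is.data.frame(tags), "kmer" %in% names(tags),
            is(primary, "GenomeKmerIndex"))
  .withSeed(seed,
    cpp_gen_errors(as.character(tags$kmer), primary@ptr, as.integer(nVariants)))
}

#' Build a tag + error k-mer database from genome assemblies
#'
#' End-to-end list building: index the primary assembly, keep k-mers unique in
#' it and in every additional assembly, drop candidates with another genomic
#' k-mer within Hamming distance 1, thin to one tag per eligible spacing
#' window, and attach randomly drawn single-mismatch error k-mers. The
#' spacing and isolation steps are fused internally (isolation is only tested
#' for candidates that can be kept, left to right within each eligible
#' window), which is exactly equivalent to
#' `filterSpacing(filterHammingIsolated(...))` but avoids testing millions of
#' candidates that the spacing filter would discard anyway.
#'
#' @param primary primary assembly: FASTA path, `XStringSet`, named character
#'   vector, or a prebuilt [GenomeKmerIndex-class].
#' @param others list of additional assemblies (same forms) that tags must
#'   also be unique in.
#' @param k k-mer length (default 25).
#' @param windowLen,keepEvery spacing filter parameters (defaults 100 bp,
#'   every third window; see [filterSpacing()]).
#' @param nVariants error-k-mer variants attempted per tag (default 4).
#' @param seed optional seed for the error-variant draw.
#' @return a [KmerDatabase-class].
#' @examples
#' set.seed(1)
#' g <- generateGenome(20000)
#' db <- buildKmerDatabase(g, k = 25)
#' db
#' @export
buildKmerDatabase <- function(primary, others = list(), k = 25,
                              windowLen = 100, keepEvery = 3,
                              nVariants = 4, seed = NULL) {
  k <- as.integer(k)
  idx <- if (is(primary, "GenomeKmerIndex")) primary else buildGenomeIndex(primary, k)
  if (idx@k != k) stop("prebuilt index has k=", idx@k, ", requested k=", k)
  if (!is.list(others)) others <- list(others)
  oidx <- lapply(others, function(o)
    if (is(o, "GenomeKmerIndex")) o else buildGenomeIndex(o, k))
  cand <- selectUniqueUniversal(idx, oidx)
  tags <- cpp_build_tags_lazy(cand@ptr, idx@ptr,
                              as.integer(windowLen), as.integer(keepEvery))
  errors <- generateErrorKmers(tags, idx, nVariants = nVariants, seed = seed)
  prov <- list(
    tool = paste0("kmerdepth ", as.character(utils::packageVersion("kmerdepth"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    k = k,
    primary = idx@source,
    others = vapply(oidx, function(o) o@source, character(1)),
    window_len = as.integer(windowLen),
    keep_every = as.integer(keepEvery),
    n_variants = as.integer(nVariants),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n_candidates = cand@n,
    n_tags = nrow(tags),
    n_errors = nrow(errors),
    tags_short_of_variants = sum(table(factor(errors$parent,
                                              levels = tags$kmer)) < nVariants)
  )
  new("KmerDatabase", k = k, tags = tags, errors = errors,
      provenance = prov, cache = new.env(parent = emptyenv()))
}

#' @rdname KmerDatabase-class
#' @param x,object a `KmerDatabase`.
#' @export
setMethod("tagKmers", "KmerDatabase", function(x) x@tags)

#' @rdname KmerDatabase-class
#' @export
setMethod("errorKmers", "KmerDatabase", function(x) x@errors)

#' @rdname KmerDatabase-class
#' @export
setMethod("provenance", "KmerDatabase", function(x) x@provenance)

#' @rdname KmerDatabase-class
#' @export
setMethod("kmerLength", "KmerDatabase", function(x) x@k)

setMethod("show", "KmerDatabase", function(object) {
  cat("KmerDatabase (k = ", object@k, ")\n", sep = "")
  cat("  tag k-mers:   ", format(nrow(object@tags), big.mark = ","), "\n", sep = "")
  cat("  error k-mers: ", format(nrow(object@errors), big.mark = ","), "\n", sep = "")
  pv <- object@provenance
  if (!is.null(pv$primary))
    cat("  primary:      ", pv$primary, "\n", sep = "")
  if (length(pv$others))
    cat("  also unique in ", length(pv$others), " other assemblies\n", sep = "")
})

# database fingerprint; cached because it hashes every k-mer string
.dbHash <- function(db) {
  h <- db@cache$hash
  if (is.null(h)) {
    h <- cpp_db_hash(db@tags$kmer, db@errors$kmer, db@k)
    db@cache$hash <- h
  }
  h
}

# native tag+error membership map; cached on the database object
.dbLookup <- function(db) {
  lk <- db@cache$lookup
  if (is.null(lk)) {
    lk <- cpp_make_lookup(db@tags$kmer, db@errors$kmer, db@k)
    db@cache$lookup <- lk
  }
  lk
}
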