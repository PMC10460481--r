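#' Generate a random genome sequence
#'
#' I.i.d. uniform ACGT sequence of the requested length, optionally with
#' engineered repeats: each element of `repeats` copies a segment of the
#' freshly generated sequence over another location, with an optional number
#' of random mismatches introduced into the copy. Repeats exercise the
#' uniqueness and Hamming-isolation filters (an exact copy kills uniqueness; a
#' 1-mismatch copy kills isolation). Randomness comes from R's RNG stream
#' (`set.seed()` for reproducibility).
#'
#' @param length genome length in bases.
#' @param repeats optional list of lists with fields `from`, `to`, `at`
#'   (1-based, inclusive; the segment `[from, to]` overwrites the equally long
#'   stretch starting at `at`) and optional `mismatches` (number of random
#'   single-base substitutions applied to the copy, default 0).
#' @param name record name (default `"g1"`).
#' @return a length-1 named `DNAStringSet`.
#' @examples
#' set.seed(1)
#' g <- generateGenome(1000, repeats = list(list(from = 100, to = 300, at = 501)))
#' @export
generateGenome <- function(length, repeats = NULL, name = "g1") {
  s <- cpp_random_genome(as.numeric(length))
  if (!is.null(repeats)) {
    for (r in repeats) {
      stopifnot(all(c("from", "to", "at") %in% names(r)))
      seg <- substr(s, r$from, r$to)
      mm <- if (is.null(r$mismatches)) 0L else as.integer(r$mismatches)
      if (mm > 0) {
        pos <- sample.int(nchar(seg), mm)
        for (p in pos) {
          cur <- substr(seg, p, p)
          alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          substr(seg, p, p) <- alt
        }
      }
      end <- r$at + nchar(seg) - 1L
      if (end > nchar(s)) stop("repeat copy extends past the genome end")
      substr(s, r$at, end) <- seg
    }
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- name
  out
}

#' Replace non-ACGT characters with random bases
#'
#' Reference assemblies contain N runs (gaps, masked regions); leaving them in
#' place would bias simulated coverage because no read window can span an N.
#' Every non-ACGT character is therefore replaced with a uniform random base
#' before simulation; ACGT (and acgt) positions are untouched.
#'
#' @param x sequences: character vector, `DNAString`, or `DNAStringSet`.
#' @return sanitized sequences, same container type as the input.
#' @export
sanitizeReference <- function(x) {
  if (methods::is(x, "XStringSet") || methods::is(x, "XString")) {
    seqs <- .asSequences(x)
    out <- Biostrings::DNAStringSet(cpp_sanitize(unname(seqs)))
    names(out) <- names(seqs)
    return(out)
  }
  out <- cpp_sanitize(as.character(x))
  names(out) <- names(x)
  out
}

#' Simulate uniform fixed-length shotgun reads
#'
#' Draws `round(depth * L / readLength)` reads (round-half-to-even), each a
#' `readLength`-bp window starting uniformly on `[0, L - readLength]`, taken
#' from a uniformly chosen strand. Per base, mutually exclusive events: the
#' base becomes `N` with probability `pN`, one of the three other bases with
#' probability `pSub` (uniformly), and is otherwise unchanged. For
#' multi-record genomes reads are allocated to records proportionally to
#' record length. Non-ACGT characters in the input propagate as `N`; sanitize
#' references first ([sanitizeReference()]).
#'
#' @param genome character / `DNAString(Set)` genome (records must be at least
#'   `readLength` long).
#' @param depth target depth of coverage; `depth <= 0` yields zero reads.
#' @param readLength read length in bases (default 100).
#' @param pN per-base N-replacement probability (default 0.01).
#' @param pSub per-base substitution probability (default 0.01).
#' @param source label encoded into read names (default `"target"`).
#' @param named set to `FALSE` to skip read-name generation (faster in tight
#'   replicate loops; counting ignores names).
#' @return character vector of read sequences; if `named`, names encode
#'   `source:record:start0:strand:serial` (0-based start on the forward
#'   strand).
#' @export
simulateReads <- function(genome, depth, readLength = 100, pN = 0.01,
                          pSub = 0.01, source = "target", named = TRUE) {
  seqs <- .asSequences(genome, "genome")
  readLength <- as.integer(readLength)
  lens <- nchar(seqs)
  if (any(lens < readLength))
    stop("every record must be at least readLength (", readLength, ") long")
  nTotal <- round(depth * sum(lens) / readLength)
  if (nTotal <= 0) return(stats::setNames(character(0), character(0)))
  perRec <- if (length(seqs) == 1L) {
    nTotal
  } else {
    as.integer(rmultinom(1, nTotal, prob = lens / sum(lens)))
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (perRec[i] == 0) { out[[i]] <- character(0); next }
    sim <- cpp_simulate_reads(unname(seqs[i]), as.integer(perRec[i]),
                              readLength, pN, pSub)
    reads <- sim$read
    if (named) {
      names(reads) <- sprintf("%s:%s:%d:%s:%d", source, names(seqs)[i],
                              sim$start, c("+", "-")[sim$strand + 1L],
                              seq_along(reads))
    }
    out[[i]] <- reads
  }
  unlist(out, use.names = named)
}

#' Mix target reads with simulated contamination
#'
#' Adds reads simulated from foreign genomes so that the target accounts for
#' `humanFraction` of the sample's nucleotides: total contaminant nucleotides
#' equal `target_nt * (1 - f) / f`, split equally (by nucleotides) among the
#' contaminant genomes, each simulated with the same read length and error
#' model. The combined read set is shuffled deterministically under the
#' caller's RNG stream. `humanFraction = 1` returns the target reads (up to
#' shuffling), ignoring any contaminants with a note.
#'
#' @param targetReads character vector of target reads (from
#'   [simulateReads()]).
#' @param contaminants list of contaminant genomes (character /
#'   `DNAString(Set)`).
#' @param humanFraction fraction of sample nucleotides from the target, in
#'   `(0, 1]`.
#' @param readLength,pN,pSub read/error model for the contaminant reads
#'   (defaults as in [simulateReads()]).
#' @param named propagate read names (see [simulateReads()]).
#' @return shuffled character vector of reads.
#' @export
composeSample <- function(targetReads, contaminants, humanFraction,
                          readLength = 100, pN = 0.01, pSub = 0.01,
                          named = TRUE) {
  stopifnot(humanFraction > 0, humanFraction <= 1)
  if (humanFraction == 1) {
    if (length(contaminants))
      message("humanFraction = 1: contaminant genomes ignored")
    return(targetReads[sample.int(length(targetReads))])
  }
  if (!is.list(contaminants)) contaminants <- list(contaminants)
  if (!length(contaminants))
    stop("humanFraction < 1 requires at least one contaminant genome")
  targetNt <- sum(nchar(targetReads))
  ntPer <- targetNt * (1 - humanFraction) / humanFraction / length(contaminants)
  all <- vector("list", length(contaminants) + 1L)
  all[[1]] <- targetReads
  for (i in seq_along(contaminants)) {
    g <- .asSequences(contaminants[[i]], "contaminant genome")
    depth <- ntPer / sum(nchar(g))
    all[[i + 1L]] <- simulateReads(g, depth, readLength = readLength, pN = pN,
                                   pSub = pSub,
                                   source = paste0("contam", i), named = named)
  }
  reads <- unlist(all, use.names = named)
  reads[sample.int(length(reads))]
}

#' Write reads as FASTQ
#'
#' Writes a character vector of reads as FASTQ with a constant dummy quality
#' line (`I` characters; qualities are ignored by the counter). Read names are
#' used as record identifiers (unnamed reads get serial numbers).
#'
#' @param reads character vector of read sequences (optionally named).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  nm <- names(reads)
  if (is.null(nm)) nm <- paste0("read", seq_along(reads))
  con <- if (.isGz(path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads))
  writeLines(paste0("@", nm, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}
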