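# Independent oracles used across the test suite. Everything here is
# deliberately naive (string-based, O(n^2)) and shares no code with the
# package's packed-word implementation.

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracleRevComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# locale-proof lexicographic min of word and reverse complement: map bases to
# digits so collation order is fixed
oracleCanonical <- function(x) {
  rc <- oracleRevComp(x)
  ifelse(chartr("ACGT", "1234", x) <= chartr("ACGT", "1234", rc), x, rc)
}

oracleHamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# min Hamming distance between two k-mer families (either orientation)
oracleMinDist <- function(a, b) {
  min(oracleHamming(a, b), oracleHamming(a, oracleRevComp(b)))
}

# naive sliding-window scan: canonical k-mers of ACGT-only windows + tallies
oracleScan <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) {
    return(list(position = integer(0), kmer = character(0),
                n_nucl = L, n_kmer = 0))
  }
  starts <- seq_len(L - k + 1)
  w <- substring(seq, starts, starts + k - 1)
  valid <- !grepl("[^ACGT]", w)
  list(position = starts[valid] - 1L,
       kmer = if (any(valid)) oracleCanonical(w[valid]) else character(0),
       n_nucl = L, n_kmer = sum(valid))
}

# windows of every record of a (named) genome, one row per window
oracleGenomeWindows <- function(seqs, k) {
  do.call(rbind, lapply(names(seqs), function(nm) {
    sc <- oracleScan(seqs[[nm]], k)
    if (!length(sc$kmer)) return(NULL)
    data.frame(kmer = sc$kmer, record = nm, position = sc$position,
               stringsAsFactors = FALSE)
  }))
}

# brute-force list-building pipeline: uniqueness by dictionary, isolation by
# all-pairs Hamming over distinct genomic k-mer families, spacing by direct
# window partition. Only usable on toy genomes (O(n^2) in distinct k-mers).
oraclePipeline <- function(seqs, k, others = list(),
                           windowLen = 100, keepEvery = 3) {
  all <- oracleGenomeWindows(seqs, k)
  cnt <- table(all$kmer)
  cand <- all[all$kmer %in% names(cnt)[cnt == 1], , drop = FALSE]
  for (o in others) {
    ow <- oracleGenomeWindows(o, k)
    ocnt <- table(ow$kmer)
    cand <- cand[cand$kmer %in% names(ocnt)[ocnt == 1], , drop = FALSE]
  }
  distinct <- unique(all$kmer)
  M <- do.call(rbind, strsplit(distinct, ""))
  Mrc <- do.call(rbind, strsplit(oracleRevComp(distinct), ""))
  isolated <- vapply(cand$kmer, function(cm) {
    cv <- strsplit(cm, "")[[1]]
    cmat <- matrix(cv, nrow(M), k, byrow = TRUE)
    d <- pmin(rowSums(M != cmat), rowSums(Mrc != cmat))
    d[distinct == cm] <- Inf  # same family under canonical counting
    all(d >= 2)
  }, logical(1))
  cand <- cand[isolated, , drop = FALSE]
  cand <- cand[order(cand$record, cand$position), , drop = FALSE]
  win <- cand$position %/% windowLen
  cand <- cand[win %% keepEvery == 0, , drop = FALSE]
  keep <- !duplicated(paste(cand$record, cand$position %/% windowLen))
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$window_1mb <- out$position %/% 1000000L
  out
}

# per-tag occurrence count by exhaustive (overlapping) substring search of the
# tag and its reverse complement in every read
oracleCountTags <- function(tags, reads) {
  rs <- Biostrings::DNAStringSet(reads)
  vapply(tags, function(tg) {
    sum(Biostrings::vcountPattern(tg, rs)) +
      sum(Biostrings::vcountPattern(oracleRevComp(tg), rs))
  }, numeric(1))
}

# build a small database from an in-memory genome with the real pipeline
dbFromGenome <- function(seqs, k = 25, ...) {
  buildKmerDatabase(seqs, k = k, ...)
}
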