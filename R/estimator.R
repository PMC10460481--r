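#' Poisson-tail count cutoff against contaminant-shared k-mers
#'
#' If a contaminant genome happens to contain (or nearly contain) a database
#' k-mer, that k-mer's count is inflated by the contaminant's depth rather
#' than the target's. The cutoff is chosen so that, under the fitted count
#' model, the probability of seeing even one k-mer in the whole list at or
#' above the cutoff is below `alpha` (union bound over the list): the smallest
#' integer `c >= 1` with `listSize * P(X >= c) < alpha`, `X ~ Poisson(lambda)`.
#' `lambda` is the trimmed mean of the observed per-k-mer counts (the top
#' `trim` fraction is dropped first so that contaminant-inflated outliers do
#' not inflate the cutoff itself). All-zero (or fully trimmed) counts give
#' `lambda = 0` and cutoff 1, with a note.
#'
#' @param counts numeric vector of per-k-mer observed counts.
#' @param listSize number of k-mers in the list (default `length(counts)`).
#' @param alpha tail probability bound (default 0.01, i.e. 1%).
#' @param trim fraction of top counts dropped before averaging (default 0.01).
#' @return integer cutoff, with attribute `lambda` (the trimmed mean used).
#' @export
computeCutoff <- function(counts, listSize = length(counts), alpha = 0.01,
                          trim = 0.01) {
  stopifnot(listSize >= 1, alpha > 0, alpha < 1, trim >= 0, trim < 1)
  n <- length(counts)
  if (n == 0) stop("empty count vector")
  nDrop <- floor(n * trim)
  lambda <- if (nDrop > 0) {
    mean(sort(counts, decreasing = TRUE)[(nDrop + 1):n])
  } else {
    mean(counts)
  }
  if (!is.finite(lambda) || lambda <= 0) {
    message("all (trimmed) counts are zero; returning cutoff 1")
    return(structure(1L, lambda = 0))
  }
  # smallest c >= 1 with listSize * P(X >= c) < alpha;
  # jump near the quantile, then fix up exactly
  cc <- max(1L, as.integer(qpois(alpha / listSize, lambda,
                                 lower.tail = FALSE)) - 1L)
  tail <- function(c) ppois(c - 1, lambda, lower.tail = FALSE)
  while (listSize * tail(cc) >= alpha) cc <- cc + 1L
  while (cc > 1L && listSize * tail(cc - 1L) < alpha) cc <- cc - 1L
  structure(cc, lambda = lambda)
}

#' Apply a count cutoff to a k-mer list
#'
#' K-mers whose count strictly exceeds the cutoff are eliminated from both the
#' sample (their counts are discarded) and the list (the denominator shrinks
#' by the number removed); counts exactly at the cutoff are retained.
#'
#' @param counts numeric vector of per-k-mer counts.
#' @param cutoff integer cutoff (from [computeCutoff()]).
#' @return list with elements `counts` (retained counts) and `nRemoved`.
#' @export
applyCutoff <- function(counts, cutoff) {
  stopifnot(cutoff >= 1)
  keep <- counts <= cutoff
  list(counts = counts[keep], nRemoved = sum(!keep))
}

#' Sequencing error rate from tag and error k-mer depths
#'
#' With unbiased errors each nucleotide has probability `P_e` of reading as a
#' false base (one of the three alternatives). Per covering read window a
#' specific error variant then appears with probability
#' `(P_e/3) * (1 - P_e)^(k-1)` and the intact tag with probability
#' `(1 - P_e)^k`, so `D_err / D_tag = (P_e/3) / (1 - P_e)`, which inverts to
#'
#' \deqn{P_e = D_{err} / (D_{err} + D_{tag} / 3).}
#'
#' `P_e` counts false nucleotides only, not N calls: windows lost to N never
#' reach either list, so N-loss cancels from the ratio.
#'
#' @param dTag mean tag k-mer count over the (retained) tag list.
#' @param dErr mean error k-mer count over the (retained) error list.
#' @return estimated error rate in `[0, 1]`.
#' @export
estimateErrorRate <- function(dTag, dErr) {
  stopifnot(dTag >= 0, dErr >= 0)
  if (dTag == 0 && dErr == 0)
    stop("undefined estimate: no tag or error k-mers observed (no usable signal)")
  dErr / (dErr + dTag / 3)
}

#' Depth of coverage from the tag k-mer depth
#'
#' The mean tag count `D_tag` measures depth at the k-mer-window level, thinned
#' by substitution errors. Scaling by `n_nucl / n_kmer` converts windows back
#' to nucleotides (correcting for read-edge and N-induced window loss), and
#' dividing by `(1 - P_e)^k` undoes the error thinning:
#'
#' \deqn{D = D_{tag} N_{nucl} / ((1 - P_e)^k N_{kmer}).}
#'
#' @param dTag mean tag k-mer count over the retained tag list.
#' @param pe estimated error rate (`0 <= pe < 1`).
#' @param k k-mer length.
#' @param n_nucl,n_kmer sample tallies (see [KmerCounts-class]).
#' @return estimated depth of coverage.
#' @export
estimateDepth <- function(dTag, pe, k, n_nucl, n_kmer) {
  stopifnot(dTag >= 0, pe >= 0, pe < 1, k >= 1)
  if (n_kmer < 1)
    stop("undefined estimate: no k-mer windows in sample (n_kmer = 0)")
  dTag * n_nucl / ((1 - pe)^k * n_kmer)
}

#' Estimate depth of coverage and error rate from k-mer counts
#'
#' Full estimation pipeline: (1) a Poisson-tail cutoff is computed and applied
#' separately to the tag and the error list (their expected counts differ by a
#' factor of about `P_e/3`, so one shared cutoff would be wrong for both);
#' (2) the mean per-k-mer depths `D_tag`, `D_err` are computed over the
#' retained lists; (3) the error rate and then the depth are estimated from
#' the closed-form expressions (see [estimateErrorRate()], [estimateDepth()]).
#'
#' @param counts a [KmerCounts-class] produced against `db`.
#' @param db the [KmerDatabase-class].
#' @param alpha cutoff tail probability bound (default 0.01).
#' @param trim trimmed-mean fraction for the cutoff rate (default 0.01).
#' @return a [DepthEstimate-class].
#' @examples
#' set.seed(7)
#' g <- generateGenome(200000)
#' db <- buildKmerDatabase(g, k = 25)
#' reads <- simulateReads(g, depth = 2)
#' est <- runEstimation(countReads(reads, db), db)
#' est
#' @export
runEstimation <- function(counts, db, alpha = 0.01, trim = 0.01) {
  stopifnot(is(counts, "KmerCounts"), is(db, "KmerDatabase"))
  if (!identical(counts@dbHash, .dbHash(db)))
    stop("counts were not produced against this database")
  if (counts@nReads == 0)
    stop("undefined estimate: sample contains zero reads")
  if (counts@nKmer < 1)
    stop("undefined estimate: no k-mer windows in sample (n_kmer = 0)")
  tc <- counts@tagCounts
  ec <- counts@errCounts
  if (length(tc) == 0) stop("database has an empty tag list")
  cutT <- computeCutoff(tc, length(tc), alpha = alpha, trim = trim)
  appT <- applyCutoff(tc, cutT)
  if (length(appT$counts) == 0)
    stop("undefined estimate: cutoff removed every tag k-mer")
  dTag <- mean(appT$counts)
  if (length(ec) > 0) {
    cutE <- computeCutoff(ec, length(ec), alpha = alpha, trim = trim)
    appE <- applyCutoff(ec, cutE)
    dErr <- if (length(appE$counts)) mean(appE$counts) else 0
  } else {
    cutE <- structure(1L, lambda = 0)
    appE <- list(counts = numeric(0), nRemoved = 0)
    dErr <- 0
  }
  pe <- estimateErrorRate(dTag, dErr)
  depth <- estimateDepth(dTag, pe, db@k, counts@nNucl, counts@nKmer)
  new("DepthEstimate",
      depth = depth, errorRate = pe, dTag = dTag, dErr = dErr,
      cutoffTag = as.integer(cutT), cutoffErr = as.integer(cutE),
      nTagUsed = as.integer(length(appT$counts)),
      nErrUsed = as.integer(length(appE$counts)),
      nTagRemoved = as.integer(appT$nRemoved),
      nErrRemoved = as.integer(appE$nRemoved),
      nNucl = counts@nNucl, nKmer = counts@nKmer, nReads = counts@nReads,
      provenance = c(db@provenance,
                     list(alpha = alpha, trim = trim,
                          lambda_tag = as.numeric(attr(cutT, "lambda")),
                          lambda_err = as.numeric(attr(cutE, "lambda")))))
}

#' @rdname DepthEstimate-class
#' @param x,object a `DepthEstimate`.
#' @export
setMethod("depthOfCoverage", "DepthEstimate", function(x) x@depth)

#' @rdname DepthEstimate-class
#' @export
setMethod("errorRate", "DepthEstimate", function(x) x@errorRate)

#' @rdname DepthEstimate-class
#' @export
setMethod("provenance", "DepthEstimate", function(x) x@provenance)

setMethod("show", "DepthEstimate", function(object) {
  cat("DepthEstimate\n")
  cat(sprintf("  depth of coverage (D):   %.6g\n", object@depth))
  cat(sprintf("  error rate (P_e):        %.6g\n", object@errorRate))
  cat(sprintf("  D_tag: %.6g over %d tags (cutoff %d, removed %d)\n",
              object@dTag, object@nTagUsed, object@cutoffTag, object@nTagRemoved))
  cat(sprintf("  D_err: %.6g over %d error k-mers (cutoff %d, removed %d)\n",
              object@dErr, object@nErrUsed, object@cutoffErr, object@nErrRemoved))
  cat(sprintf("  sample: %.0f reads, n_nucl = %.0f, n_kmer = %.0f\n",
              object@nReads, object@nNucl, object@nKmer))
})

# flat list view used for the JSON report
.estimateAsList <- function(est) {
  list(depth = est@depth,
       error_rate = est@errorRate,
       d_tag = est@dTag,
       d_err = est@dErr,
       cutoff_tag = est@cutoffTag,
       cutoff_err = est@cutoffErr,
       n_tag_used = est@nTagUsed,
       n_err_used = est@nErrUsed,
       n_tag_removed = est@nTagRemoved,
       n_err_removed = est@nErrRemoved,
       n_nucl = est@nNucl,
       n_kmer = est@nKmer,
       n_reads = est@nReads,
       db_provenance = est@provenance)
}

#' Write an estimate report as JSON
#'
#' Writes the [DepthEstimate-class] as a JSON object with keys `depth`,
#' `error_rate`, `d_tag`, `d_err`, `cutoff_tag`, `cutoff_err`, `n_tag_used`,
#' `n_err_used`, `n_tag_removed`, `n_err_removed`, `n_nucl`, `n_kmer`,
#' `n_reads` and `db_provenance`.
#'
#' @param est a [DepthEstimate-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEstimateReport <- function(est, path) {
  stopifnot(is(est, "DepthEstimate"))
  jsonlite::write_json(.estimateAsList(est), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
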