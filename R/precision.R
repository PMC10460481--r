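#' Replicate-pooled depth estimation on simulated samples
#'
#' Runs `nReplicates` independent simulations of the same condition (target
#' depth, contamination level), pools the k-mer counts by field-wise addition,
#' and estimates once from the pooled counts. Pooling replicates multiplies
#' the tag and error hit totals, shrinking the stochastic error of the
#' estimate by roughly `1/sqrt(nReplicates)`; it is how low-depth precision is
#' assessed on genomes much smaller than a full human assembly. All randomness
#' flows from the caller's RNG stream.
#'
#' @param db a [KmerDatabase-class] built from `genome`.
#' @param genome the target genome (character / `DNAString(Set)`).
#' @param depth simulated target depth of coverage per replicate.
#' @param nReplicates number of replicates pooled.
#' @param humanFraction fraction of sample nucleotides from the target
#'   (default 1 = no contamination).
#' @param contaminants list of contaminant genomes (required when
#'   `humanFraction < 1`).
#' @param readLength,pN,pSub simulation parameters (see [simulateReads()]).
#' @param alpha cutoff tail bound passed to [runEstimation()].
#' @return a [DepthEstimate-class] computed from the pooled counts. Pooled
#'   counts add up across replicates, so the raw pooled estimate measures
#'   `nReplicates` times the per-replicate depth; the returned `depth` slot is
#'   rescaled to the per-replicate depth (directly comparable to `depth`),
#'   with the replicate count recorded in the provenance. The error rate is a
#'   ratio and needs no rescaling.
#' @export
pooledDepthEstimate <- function(db, genome, depth, nReplicates,
                                humanFraction = 1, contaminants = list(),
                                readLength = 100, pN = 0.01, pSub = 0.01,
                                alpha = 0.01) {
  stopifnot(is(db, "KmerDatabase"), nReplicates >= 1)
  genome <- .asSequences(genome, "genome")
  contaminants <- lapply(if (is.list(contaminants)) contaminants
                         else list(contaminants), .asSequences)
  pooled <- NULL
  for (i in seq_len(nReplicates)) {
    reads <- simulateReads(genome, depth, readLength = readLength,
                           pN = pN, pSub = pSub, named = FALSE)
    if (humanFraction < 1) {
      reads <- composeSample(reads, contaminants, humanFraction,
                             readLength = readLength, pN = pN, pSub = pSub,
                             named = FALSE)
    }
    cc <- countReads(reads, db)
    pooled <- if (is.null(pooled)) cc else mergeCounts(pooled, cc)
  }
  est <- runEstimation(pooled, db, alpha = alpha)
  est@depth <- est@depth / nReplicates
  est@provenance <- c(est@provenance,
                      list(n_replicates = nReplicates,
                           depth_scale = "per replicate"))
  validObject(est)
  est
}

#' Precision experiment over a depth x contamination grid
#'
#' Self-contained driver for the precision study: generates a random target
#' genome and contaminant genomes, builds the k-mer database, and for every
#' combination of simulated depth and human fraction runs `replicates`
#' independent simulate-count-estimate rounds (one estimate per replicate, not
#' pooled), recording relative errors of the depth and error-rate estimates.
#' The output table is tidy, one row per (depth, fraction, replicate),
#' sufficient to draw precision-vs-depth curves per contamination level.
#'
#' @param genomeLength target genome length in bases.
#' @param depths vector of simulated depths (default the standard grid
#'   0.001--0.333).
#' @param humanFractions vector of target-nucleotide fractions in `(0, 1]`
#'   (default `c(0.1, 1)`; 0.1 means 10x contamination).
#' @param replicates independent simulations per grid cell (default 3).
#' @param k k-mer length (default 25).
#' @param contaminantLengths lengths of the synthetic contaminant genomes
#'   (default three of 1 Mb).
#' @param readLength,pN,pSub simulation parameters (see [simulateReads()]).
#' @param alpha cutoff tail bound (see [computeCutoff()]).
#' @return `data.frame` with columns `depth_true`, `human_fraction`,
#'   `replicate`, `depth_est`, `depth_rel_err`, `pe_est`, `pe_rel_err`.
#'   Relative errors are `estimate/truth - 1` with truth `depth_true` and
#'   `pSub`; cells with no usable signal give `NA`.
#' @export
precisionGrid <- function(genomeLength,
                          depths = c(0.001, 0.0033, 0.01, 0.033, 0.1, 0.333),
                          humanFractions = c(0.1, 1),
                          replicates = 3, k = 25,
                          contaminantLengths = c(1e6, 1e6, 1e6),
                          readLength = 100, pN = 0.01, pSub = 0.01,
                          alpha = 0.01) {
  genome <- .asSequences(generateGenome(genomeLength, name = "target"))
  contams <- lapply(seq_along(contaminantLengths), function(i)
    .asSequences(generateGenome(contaminantLengths[i], name = paste0("contam", i))))
  db <- buildKmerDatabase(genome, k = k)
  grid <- expand.grid(depth_true = depths, human_fraction = humanFractions,
                      replicate = seq_len(replicates))
  grid <- grid[order(grid$depth_true, grid$human_fraction, grid$replicate), ,
               drop = FALSE]
  rownames(grid) <- NULL
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$depth_true[i]
    f <- grid$human_fraction[i]
    est <- tryCatch({
      reads <- simulateReads(genome, d, readLength = readLength, pN = pN,
                             pSub = pSub, named = FALSE)
      if (f < 1)
        reads <- composeSample(reads, contams, f, readLength = readLength,
                               pN = pN, pSub = pSub, named = FALSE)
      runEstimation(countReads(reads, db), db, alpha = alpha)
    }, error = function(e) NULL)
    if (is.null(est))
      return(data.frame(depth_est = NA_real_, depth_rel_err = NA_real_,
                        pe_est = NA_real_, pe_rel_err = NA_real_))
    data.frame(depth_est = est@depth,
               depth_rel_err = est@depth / d - 1,
               pe_est = est@errorRate,
               pe_rel_err = est@errorRate / pSub - 1)
  })
  cbind(grid, do.call(rbind, res))
}
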