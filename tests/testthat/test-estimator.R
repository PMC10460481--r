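test_that("poisson-tail cutoff matches direct tail evaluation", {
  # lambda = 0.01, list of 1e6, alpha 1%: smallest c with 1e6 * P(X >= c) < 0.01
  # is 4 (P(X>=3) = 1.66e-7 -> 0.166 >= 0.01; P(X>=4) = 4.2e-10 -> 4.2e-4 < 0.01)
  counts <- rep(0.01, 1e4)  # trimmed mean is exactly 0.01 (constant counts)
  cc <- computeCutoff(counts, listSize = 1e6, alpha = 0.01, trim = 0)
  expect_identical(as.integer(cc), 4L)
  # degenerate all-zero counts
  expect_message(c0 <- computeCutoff(rep(0, 100), 100), "cutoff 1")
  expect_identical(as.integer(c0), 1L)
  # monotone in lambda and in list size
  lams <- c(0.01, 0.1, 0.5, 2, 10, 50)
  cuts <- vapply(lams, function(l)
    as.integer(computeCutoff(rep(l, 10), listSize = 1e5, trim = 0)), integer(1))
  expect_true(all(diff(cuts) >= 0))
  sizes <- c(1e2, 1e4, 1e6, 1e8)
  cutsN <- vapply(sizes, function(n)
    as.integer(computeCutoff(rep(0.5, 10), listSize = n, trim = 0)), integer(1))
  expect_true(all(diff(cutsN) >= 0))
  # definition check on a grid: returned c is minimal and satisfies the bound
  for (l in c(0.05, 1.3, 7)) {
    for (n in c(10, 1e4, 1e7)) {
      cv <- as.integer(computeCutoff(rep(l, 10), listSize = n, trim = 0))
      expect_lt(n * ppois(cv - 1, l, lower.tail = FALSE), 0.01)
      if (cv > 1)
        expect_gte(n * ppois(cv - 2, l, lower.tail = FALSE), 0.01)
    }
  }
})

test_that("cutoff removal drops high counts from sample and list alike", {
  app <- applyCutoff(c(0, 1, 1, 9), 3)
  expect_equal(app$counts, c(0, 1, 1))
  expect_equal(app$nRemoved, 1)
  # ties at the cutoff are retained; cutoff >= max is the identity
  expect_equal(applyCutoff(c(0, 3, 3), 3)$nRemoved, 0)
  expect_equal(applyCutoff(c(5, 2, 7), 7)$counts, c(5, 2, 7))
})

test_that("error-rate and depth formulas match direct arithmetic", {
  expect_equal(estimateErrorRate(0.3, 0), 0)
  expect_equal(estimateErrorRate(0.3, 0.001), 0.001 / (0.001 + 0.1))
  expect_error(estimateErrorRate(0, 0), "no usable signal")
  expect_equal(estimateDepth(1, 0, 25, 100, 100), 1)
  # 0.5 * 100 / (0.99^25 * 76); 0.99^25 = 0.7778213594
  expect_equal(estimateDepth(0.5, 0.01, 25, 100, 76), 0.8458172675,
               tolerance = 1e-9)
  expect_error(estimateDepth(0.5, 0.01, 25, 100, 0), "n_kmer")
  # strictly increasing in the error rate
  ds <- vapply(c(0, 0.005, 0.01, 0.02, 0.05), function(p)
    estimateDepth(0.5, p, 25, 100, 76), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("estimators invert exact expected counts to machine precision", {
  # with D_tag = lambda (1-p)^k s and D_err = lambda (p/3) (1-p)^(k-1) s the
  # error-rate formula returns p exactly, and the depth formula returns
  # lambda * s * n_nucl / n_kmer
  set.seed(601)
  for (i in 1:50) {
    lambda <- runif(1, 1e-4, 30)
    p <- runif(1, 0, 0.5)
    s <- runif(1, 0.1, 10)
    k <- sample(5:32, 1)
    dTag <- lambda * (1 - p)^k * s
    dErr <- lambda * (p / 3) * (1 - p)^(k - 1) * s
    pe <- estimateErrorRate(dTag, dErr)
    expect_equal(pe, p, tolerance = 1e-12)
    nn <- runif(1, 1e4, 1e8)
    nk <- runif(1, 1e3, nn)
    expect_equal(estimateDepth(dTag, pe, k, nn, nk),
                 lambda * s * nn / nk, tolerance = 1e-12)
  }
})

test_that("depth and error rate are recovered from simulated reads", {
  set.seed(602)
  g <- c(g1 = randSeq(1e6))
  db <- buildKmerDatabase(g, k = 25, seed = 2)
  pooled <- NULL
  nrep <- 25
  for (i in seq_len(nrep)) {
    reads <- simulateReads(g, depth = 0.1, named = FALSE)
    cc <- countReads(reads, db)
    pooled <- if (is.null(pooled)) cc else mergeCounts(pooled, cc)
  }
  est <- runEstimation(pooled, db)
  dHat <- depthOfCoverage(est) / nrep
  # stochastic tolerance from the realized hit totals (3 standard errors,
  # error-rate noise propagated through (1-Pe)^-k)
  seTag <- 1 / sqrt(sum(tagCounts(pooled)))
  seErr <- 1 / sqrt(max(1, sum(errorCounts(pooled))))
  seDepth <- sqrt(seTag^2 + (25 * errorRate(est) * seErr)^2)
  expect_lt(abs(dHat / 0.1 - 1), 3 * seDepth)
  # Pe converges to pSub / (1 - pN): substitutions among non-N bases
  peTrue <- 0.01 / 0.99
  expect_lt(abs(errorRate(est) / peTrue - 1), 3 * seErr + 0.01)
  # diagnostics are consistent
  expect_identical(est@nTagUsed + est@nTagRemoved, nrow(tagKmers(db)))
  expect_identical(est@nErrUsed + est@nErrRemoved, nrow(errorKmers(db)))
})

test_that("doubling the sample doubles the pooled depth estimate", {
  set.seed(603)
  g <- c(g1 = randSeq(3e5))
  db <- buildKmerDatabase(g, k = 25, seed = 2)
  cc <- countReads(simulateReads(g, depth = 1, named = FALSE), db)
  twice <- mergeCounts(cc, cc)
  # trim = 0 keeps the outlier-trimming heuristic out of a clean-sample
  # property check (sparse error counts would otherwise be fully trimmed)
  e1 <- runEstimation(cc, db, trim = 0)
  e2 <- runEstimation(twice, db, trim = 0)
  # identical correction factors, doubled counts (up to cutoff granularity)
  expect_equal(depthOfCoverage(e2) / depthOfCoverage(e1), 2, tolerance = 0.01)
  expect_equal(errorRate(e2), errorRate(e1), tolerance = 0.05)
})

test_that("the cutoff removes contaminant-inflated tags and restores the estimate", {
  set.seed(604)
  g <- c(g1 = randSeq(2e5))
  db <- buildKmerDatabase(g, k = 25, seed = 2)
  reads <- simulateReads(g, depth = 1, named = FALSE)
  # a high-abundance contaminant genome sharing one tag k-mer's region,
  # sequenced with the same read/error model as the target
  tag10 <- tagKmers(db)[10, ]
  region <- substr(g[[1]], tag10$position + 1 - 30, tag10$position + 25 + 30)
  contGenome <- c(c1 = paste0(randSeq(400), region, randSeq(400)))
  contamReads <- simulateReads(contGenome, depth = 600, named = FALSE)
  shared <- tag10$kmer
  ccClean <- countReads(reads, db)
  ccCont <- mergeCounts(ccClean, countReads(contamReads, db))
  eClean <- runEstimation(ccClean, db)
  eCont <- runEstimation(ccCont, db)
  # the shared tag is eliminated, not averaged in
  expect_gte(eCont@nTagRemoved, 1)
  expect_gt(max(tagCounts(ccCont)), eCont@cutoffTag)
  # without the cutoff the same counts are badly biased ...
  dTagNaive <- mean(tagCounts(ccCont))
  naive <- estimateDepth(dTagNaive, errorRate(eCont), 25, nNucl(ccCont), nKmer(ccCont))
  expect_gt(naive / depthOfCoverage(eClean), 1.5)
  # ... while the cutoff moves the estimate most of the way back to the clean
  # value (the residual gap comes from contaminant hits on the shared tag's
  # few error variants, material only at this toy list size)
  expect_lt(abs(depthOfCoverage(eCont) - depthOfCoverage(eClean)),
            0.25 * abs(naive - depthOfCoverage(eClean)))
})

test_that("cutoff removes almost nothing from clean homogeneous samples", {
  set.seed(605)
  g <- c(g1 = randSeq(2e5))
  db <- buildKmerDatabase(g, k = 25, seed = 2)
  alpha <- 0.01
  fracRemoved <- vapply(1:20, function(i) {
    cc <- countReads(simulateReads(g, depth = 2, named = FALSE), db)
    est <- runEstimation(cc, db, alpha = alpha)
    est@nTagRemoved / nrow(tagKmers(db))
  }, numeric(1))
  expect_lte(mean(fracRemoved), 2 * alpha)
})

test_that("degenerate inputs raise undefined-estimate errors", {
  set.seed(606)
  g <- c(g1 = randSeq(50000))
  db <- buildKmerDatabase(g, k = 25, seed = 2)
  empty <- countReads(character(0), db)
  expect_error(runEstimation(empty, db), "zero reads")
  db2 <- buildKmerDatabase(c(g1 = randSeq(50000)), k = 25, seed = 2)
  cc <- countReads(simulateReads(g, 0.5, named = FALSE), db)
  expect_error(runEstimation(cc, db2), "not produced against this database")
})
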