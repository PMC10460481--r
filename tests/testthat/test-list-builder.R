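test_that("genome indexing matches hand enumeration and the scan oracle", {
  # ACGTACGT, k=5: windows ACGTA,CGTAC,GTACG,TACGT collapse to 2 canonical pairs
  idx <- buildGenomeIndex(c(chr1 = "ACGTACGT"), k = 5)
  expect_equal(idx@nWindows, 4)
  expect_equal(idx@nDistinct, 2)
  expect_equal(unname(kmerCount(idx, c("ACGTA", "CGTAC", "GTACG", "TACGT"))),
               c(2, 2, 2, 2))
  expect_equal(unname(kmerCount(idx, "AAAAA")), 0)

  set.seed(301)
  g <- randSeq(1000)
  idx2 <- buildGenomeIndex(c(g1 = g), k = 25)
  expect_equal(idx2@nWindows, 976)  # L - k + 1

  # record with N runs: counts equal the naive window oracle
  gn <- paste0(substr(g, 1, 300), "NNNN", substr(g, 301, 600), "N",
               substr(g, 601, 1000))
  idx3 <- buildGenomeIndex(c(g1 = gn), k = 25)
  want <- oracleScan(gn, 25)
  expect_equal(idx3@nWindows, want$n_kmer)
  tab <- table(want$kmer)
  got <- as.data.frame(idx3)
  expect_setequal(got$kmer, names(tab))
  expect_equal(got$count[match(names(tab), got$kmer)], unname(as.numeric(tab)))
  # first-occurrence positions
  firstPos <- vapply(names(tab), function(km) min(want$position[want$kmer == km]),
                     numeric(1))
  expect_equal(got$position[match(names(tab), got$kmer)], unname(firstPos))
})

test_that("indexing is deterministic and rejects bad input", {
  set.seed(302)
  g <- c(r1 = randSeq(500), r2 = randSeq(300))
  a <- as.data.frame(buildGenomeIndex(g, k = 11))
  b <- as.data.frame(buildGenomeIndex(g, k = 11))
  expect_identical(a, b)
  tmp <- tempfile(fileext = ".fa")
  file.create(tmp)
  expect_error(buildGenomeIndex(tmp, k = 11), "empty|read")
  expect_error(buildGenomeIndex("/nonexistent/file.fa", k = 11), "no such file")
})

test_that("uniqueness filter keeps exactly the count-1 k-mers of all assemblies", {
  set.seed(303)
  core <- randSeq(800)
  # exact duplicated 100-base segment: nothing inside the duplication survives
  seg <- substr(core, 201, 300)
  g <- c(g1 = paste0(core, seg))
  k <- 15
  idx <- buildGenomeIndex(g, k = k)
  cand <- selectUniqueUniversal(idx)
  df <- as.data.frame(cand)
  w <- oracleGenomeWindows(g, k)
  tab <- table(w$kmer)
  expect_setequal(df$kmer, names(tab)[tab == 1])
  dupKmers <- oracleScan(seg, k)$kmer
  expect_false(any(df$kmer %in% dupKmers))

  # others = list(): vacuous universality; against another assembly sharing
  # half the sequence the result is the set-algebra intersection
  other <- c(o1 = paste0(substr(core, 1, 400), randSeq(400)))
  oidx <- buildGenomeIndex(other, k = k)
  both <- as.data.frame(selectUniqueUniversal(idx, list(oidx)))
  ow <- oracleGenomeWindows(other, k)
  otab <- table(ow$kmer)
  expect_setequal(both$kmer,
                  intersect(names(tab)[tab == 1], names(otab)[otab == 1]))
  expect_error(selectUniqueUniversal(idx, list(buildGenomeIndex(other, k = 17))),
               "mismatch")
})

test_that("hamming isolation filter equals the all-pairs oracle", {
  set.seed(304)
  k <- 15
  # segment S followed by a copy of S with one substituted base: candidates
  # overlapping the substitution in either copy must be removed
  S <- randSeq(600)
  S2 <- S
  substr(S2, 300, 300) <- setdiff(c("A", "C", "G", "T"), substr(S, 300, 300))[1]
  g <- c(g1 = paste0(S, S2, randSeq(400)))
  idx <- buildGenomeIndex(g, k = k)
  cand <- selectUniqueUniversal(idx)
  iso <- as.data.frame(filterHammingIsolated(cand, idx))

  all <- oracleGenomeWindows(g, k)
  distinct <- unique(all$kmer)
  M <- do.call(rbind, strsplit(distinct, ""))
  Mrc <- do.call(rbind, strsplit(oracleRevComp(distinct), ""))
  candDf <- as.data.frame(cand)
  keep <- vapply(candDf$kmer, function(cm) {
    cv <- matrix(strsplit(cm, "")[[1]], nrow(M), k, byrow = TRUE)
    d <- pmin(rowSums(M != cv), rowSums(Mrc != cv))
    d[distinct == cm] <- Inf
    all(d >= 2)
  }, logical(1))
  expect_identical(iso$kmer, candDf$kmer[keep])

  # candidates whose window overlaps the substituted position are gone
  subPos0 <- 299  # 0-based position of the substitution in the first copy
  hit <- candDf$position <= subPos0 & candDf$position + k - 1 >= subPos0
  expect_false(any(iso$position %in% candDf$position[hit]))
})

test_that("isolation is the identity when no two windows are within distance 1", {
  set.seed(305)
  k <- 25
  g <- c(g1 = randSeq(1500))
  all <- oracleGenomeWindows(g, k)
  distinct <- unique(all$kmer)
  M <- do.call(rbind, strsplit(distinct, ""))
  Mrc <- do.call(rbind, strsplit(oracleRevComp(distinct), ""))
  pairMin <- vapply(seq_along(distinct), function(i) {
    cv <- matrix(strsplit(distinct[i], "")[[1]], nrow(M), k, byrow = TRUE)
    d <- pmin(rowSums(M != cv), rowSums(Mrc != cv))
    d[i] <- Inf
    min(d)
  }, numeric(1))
  # verified premise: this genome has no two window families within distance 1
  expect_gte(min(pairMin), 2)
  idx <- buildGenomeIndex(g, k = k)
  cand <- selectUniqueUniversal(idx)
  iso <- filterHammingIsolated(cand, idx)
  expect_identical(as.data.frame(iso), as.data.frame(cand))
})

test_that("spacing filter keeps the leftmost candidate of every third window", {
  set.seed(306)
  g <- c(g1 = randSeq(1000))
  k <- 5  # every window of the record has candidates
  idx <- buildGenomeIndex(g, k = k)
  cand <- selectUniqueUniversal(idx)
  tags <- filterSpacing(cand, windowLen = 100, keepEvery = 3)
  df <- as.data.frame(cand)
  expect_true(all(tags$position %/% 100 %% 3 == 0))
  expect_lte(nrow(tags), 4)  # windows 0, 3, 6, 9
  for (w in unique(tags$position %/% 100)) {
    inWin <- df$position[df$position %/% 100 == w]
    expect_equal(tags$position[tags$position %/% 100 == w], min(inWin))
  }
  # pairwise spacing >= 200 within each record, on randomized inputs
  for (i in 1:5) {
    gg <- c(a = randSeq(3000), b = randSeq(2000))
    kk <- 11
    ii <- buildGenomeIndex(gg, k = kk)
    tt <- filterSpacing(selectUniqueUniversal(ii), 100, 3)
    gaps <- unlist(lapply(split(tt$position, tt$record), diff))
    if (length(gaps)) expect_true(all(gaps >= 200))
  }
})

test_that("error k-mers are distance-1 from parent, distance>=2 from the genome", {
  set.seed(307)
  g <- c(g1 = randSeq(4000))
  k <- 25
  idx <- buildGenomeIndex(g, k = k)
  db <- buildKmerDatabase(idx, k = k, seed = 42)
  er <- errorKmers(db)
  expect_gt(nrow(er), 0)
  # distance exactly 1 on appropriately oriented words
  expect_true(all(vapply(seq_len(nrow(er)), function(i)
    oracleMinDist(er$kmer[i], er$parent[i]) == 1, logical(1))))
  # absent from the genome
  expect_true(all(kmerCount(idx, er$kmer) == 0))
  # no genomic k-mer other than the parent within distance 1 (brute force)
  all <- oracleGenomeWindows(g, k)
  distinct <- unique(all$kmer)
  M <- do.call(rbind, strsplit(distinct, ""))
  Mrc <- do.call(rbind, strsplit(oracleRevComp(distinct), ""))
  for (i in sample(nrow(er), min(40, nrow(er)))) {
    cv <- matrix(strsplit(er$kmer[i], "")[[1]], nrow(M), k, byrow = TRUE)
    d <- pmin(rowSums(M != cv), rowSums(Mrc != cv))
    close <- distinct[d <= 1]
    expect_identical(close, er$parent[i])
  }
  # mm_pos/mm_base reconstruct the variant
  recon <- er$parent
  substr(recon, er$mm_pos + 1, er$mm_pos + 1) <- er$mm_base
  expect_identical(canonicalKmer(recon), er$kmer)
})

test_that("error-variant generation is seed-deterministic with ~4 variants/tag", {
  set.seed(308)
  g <- c(g1 = randSeq(20000))
  idx <- buildGenomeIndex(g, k = 25)
  tags <- filterSpacing(selectUniqueUniversal(idx), 100, 3)
  e1 <- generateErrorKmers(tags, idx, seed = 99)
  e2 <- generateErrorKmers(tags, idx, seed = 99)
  expect_identical(e1, e2)
  e3 <- generateErrorKmers(tags, idx, seed = 100)
  expect_false(identical(e1$mm_pos, e3$mm_pos))
  # at k=25 near-collisions are vanishingly rare: acceptance ~ 100%
  expect_equal(nrow(e1), 4 * nrow(tags))
  expect_false(any(e1$kmer %in% tags$kmer))
  expect_false(anyDuplicated(e1$kmer) > 0)
})

test_that("full pipeline equals the brute-force oracle on toy genomes", {
  set.seed(309)
  for (rep in 1:3) {
    S <- randSeq(500)
    S1 <- S
    substr(S1, 250, 250) <- setdiff(c("A", "C", "G", "T"), substr(S, 250, 250))[1]
    g <- c(g1 = paste0(randSeq(600), S, randSeq(100), S1),
           g2 = randSeq(700))
    k <- 13
    idx <- buildGenomeIndex(g, k = k)
    # composed ops
    composed <- filterSpacing(filterHammingIsolated(selectUniqueUniversal(idx), idx),
                              100, 3)
    # fused builder path
    db <- buildKmerDatabase(idx, k = k, seed = 5)
    # independent O(n^2) oracle
    want <- oraclePipeline(g, k)
    expect_equal(composed$kmer, want$kmer)
    expect_equal(composed$position, want$position)
    expect_equal(composed$record, want$record)
    expect_identical(tagKmers(db)[names(composed)], composed)
  }
})

test_that("database rebuilds are fully deterministic", {
  set.seed(310)
  g <- c(g1 = randSeq(30000))
  db1 <- buildKmerDatabase(g, k = 25, seed = 7)
  db2 <- buildKmerDatabase(g, k = 25, seed = 7)
  expect_identical(tagKmers(db1), tagKmers(db2))
  expect_identical(errorKmers(db1), errorKmers(db2))
  # tag/error sets disjoint, sizes bounded
  expect_lte(nrow(errorKmers(db1)), 4 * nrow(tagKmers(db1)))
  expect_length(intersect(tagKmers(db1)$kmer, errorKmers(db1)$kmer), 0L)
})
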