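test_that("random genomes are reproducible with uniform base composition", {
  set.seed(701)
  g1 <- generateGenome(10000)
  set.seed(701)
  g2 <- generateGenome(10000)
  expect_identical(as.character(g1), as.character(g2))
  set.seed(702)
  g3 <- generateGenome(10000)
  expect_false(as.character(g1)[[1]] == as.character(g3)[[1]])
  # each base frequency inside a 99% binomial interval around 1/4
  counts <- table(strsplit(as.character(g1)[[1]], "")[[1]])
  expect_setequal(names(counts), c("A", "C", "G", "T"))
  ci <- qbinom(c(0.005, 0.995), 10000, 0.25)
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
})

test_that("engineered repeats appear as constructed", {
  set.seed(703)
  g <- generateGenome(2000, repeats = list(list(from = 100, to = 300, at = 1001)))
  s <- as.character(g)[[1]]
  seg <- substr(s, 100, 300)
  expect_identical(substr(s, 1001, 1201), seg)
  # 1-mismatch copy differs in exactly one position
  set.seed(704)
  gm <- generateGenome(2000, repeats = list(list(from = 100, to = 300, at = 1001,
                                                 mismatches = 1)))
  sm <- as.character(gm)[[1]]
  expect_equal(oracleHamming(substr(sm, 100, 300), substr(sm, 1001, 1201)), 1)
})

test_that("reference sanitization replaces exactly the non-ACGT characters", {
  set.seed(705)
  out <- sanitizeReference("ACGNN")
  expect_identical(substr(out, 1, 3), "ACG")
  expect_true(grepl("^[ACGT]{5}$", out))
  clean <- "ACGTACGT"
  expect_identical(unname(sanitizeReference(clean)), clean)
  messy <- "ANRYGat-NNT"
  got <- sanitizeReference(messy)
  expect_true(grepl("^[ACGTacgt]+$", got))
  keep <- strsplit(messy, "")[[1]] %in% c("A", "C", "G", "T", "a", "c", "g", "t")
  expect_identical(strsplit(got, "")[[1]][keep], strsplit(messy, "")[[1]][keep])
  # DNAStringSet in, DNAStringSet out
  ss <- sanitizeReference(Biostrings::DNAStringSet(c(x = "ACGNNACG")))
  expect_s4_class(ss, "DNAStringSet")
  expect_false(grepl("N", as.character(ss)[[1]]))
})

test_that("read counts, placement and strands follow the sampling model", {
  set.seed(706)
  g <- generateGenome(20000)
  # n_reads = round(depth * L / readLength)
  expect_length(simulateReads(g, 0.01, named = FALSE), 2L)
  expect_length(simulateReads(g, 1, named = FALSE), 200L)
  expect_length(simulateReads(g, 0, named = FALSE), 0L)
  # with no errors every read or its reverse complement is an exact substring
  reads <- simulateReads(g, 1, pN = 0, pSub = 0)
  s <- as.character(g)[[1]]
  hits <- vapply(reads, function(r)
    grepl(r, s, fixed = TRUE) || grepl(oracleRevComp(r), s, fixed = TRUE),
    logical(1))
  expect_true(all(hits))
  # read names encode source, record, 0-based start and strand
  nm <- strsplit(names(reads)[1], ":", fixed = TRUE)[[1]]
  expect_identical(nm[1], "target")
  expect_identical(nm[2], "g1")
  start0 <- as.integer(nm[3])
  fwd <- substr(s, start0 + 1, start0 + 100)
  expect_identical(unname(reads[1]), if (nm[4] == "+") fwd else oracleRevComp(fwd))
  # both strands occur
  strands <- vapply(strsplit(names(reads), ":", fixed = TRUE), `[`, character(1), 4)
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("N and substitution rates land inside binomial confidence bounds", {
  set.seed(707)
  g <- generateGenome(50000)
  s <- as.character(g)[[1]]
  reads <- simulateReads(g, 4)  # 2000 reads = 2e5 bases
  nBases <- sum(nchar(reads))
  expect_gte(nBases, 1e5)
  chars <- strsplit(paste(reads, collapse = ""), "")[[1]]
  nN <- sum(chars == "N")
  ciN <- qbinom(c(0.005, 0.995), nBases, 0.01)
  expect_true(nN >= ciN[1] && nN <= ciN[2])
  # mismatches to the reference, over non-N positions
  info <- strsplit(names(reads), ":", fixed = TRUE)
  nMis <- 0L
  nTot <- 0L
  for (i in seq_along(reads)) {
    start0 <- as.integer(info[[i]][3])
    ref <- substr(s, start0 + 1, start0 + 100)
    if (info[[i]][4] == "-") ref <- oracleRevComp(ref)
    rv <- strsplit(reads[[i]], "")[[1]]
    fv <- strsplit(ref, "")[[1]]
    ok <- rv != "N"
    nMis <- nMis + sum(rv[ok] != fv[ok])
    nTot <- nTot + sum(ok)
  }
  ciS <- qbinom(c(0.005, 0.995), nTot, 0.01)
  expect_true(nMis >= ciS[1] && nMis <= ciS[2])
  # reads containing >= 1 N occur at rate 1 - (1-pN)^readLength
  pReadN <- mean(grepl("N", reads, fixed = TRUE))
  pExp <- 1 - 0.99^100
  ciR <- qbinom(c(0.005, 0.995), length(reads), pExp) / length(reads)
  expect_true(pReadN >= ciR[1] && pReadN <= ciR[2])
})

test_that("realized per-base coverage matches the target depth", {
  set.seed(708)
  g <- generateGenome(50000)
  depth <- 5
  reads <- simulateReads(g, depth, pN = 0, pSub = 0)
  cov <- numeric(50000)
  info <- strsplit(names(reads), ":", fixed = TRUE)
  for (i in seq_along(reads)) {
    start0 <- as.integer(info[[i]][3])
    cov[(start0 + 1):(start0 + 100)] <- cov[(start0 + 1):(start0 + 100)] + 1
  }
  mc <- mean(cov)
  expect_lt(abs(mc - depth), 3 * sqrt(depth * 100 / 50000))
})

test_that("contamination mixing hits the requested nucleotide shares", {
  set.seed(709)
  target <- generateGenome(100000, name = "t")
  contams <- lapply(1:3, function(i) generateGenome(30000, name = paste0("c", i)))
  treads <- simulateReads(target, 0.5)
  mixed <- composeSample(treads, contams, humanFraction = 0.1)
  src <- vapply(strsplit(names(mixed), ":", fixed = TRUE), `[`, character(1), 1)
  nt <- tapply(nchar(mixed), src, sum)
  targetNt <- sum(nchar(treads))
  # per contaminant: targetNt * (1-f)/f / 3 = 3 * targetNt, within one read
  for (cn in c("contam1", "contam2", "contam3"))
    expect_lt(abs(nt[[cn]] - 3 * targetNt), 100 + 1e-9)
  expect_equal(nt[["target"]], targetNt)
  # f = 1: identical to the target reads up to shuffling, with a note
  expect_message(pure <- composeSample(treads, contams, 1), "ignored")
  expect_setequal(names(pure), names(treads))
  # deterministic FASTQ bytes under a fixed seed
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  set.seed(710)
  writeFastq(composeSample(treads, contams, 0.25), f1)
  set.seed(710)
  writeFastq(composeSample(treads, contams, 0.25), f2)
  expect_identical(readLines(f1), readLines(f2))
})
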