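.newCounts <- function(db, raw, sources) {
  tc <- raw$tag_counts
  ec <- raw$err_counts
  names(tc) <- db@tags$kmer
  names(ec) <- db@errors$kmer
  new("KmerCounts", tagCounts = tc, errCounts = ec,
      nNucl = raw$n_nucl, nKmer = raw$n_kmer, nReads = raw$n_reads,
      sourceFiles = sources, dbHash = .dbHash(db))
}

#' Count database k-mers in sequencing reads
#'
#' Streams reads and looks up the canonical code of every ACGT-only k-length
#' window against the unified tag + error k-mer set; matches increment the
#' corresponding per-k-mer count. Every window is tested independently, so
#' overlapping occurrences within one read all count (with the default >= 200
#' bp tag spacing a 100 bp read can still hit at most one tag). Quality
#' strings are ignored. `countSample()` reads FASTQ files (plain or gzipped;
#' paired-end data is simply two files); `countReads()` counts an in-memory
#' character vector of read sequences.
#'
#' @param files character vector of FASTQ paths.
#' @param reads character vector of read sequences.
#' @param db a [KmerDatabase-class].
#' @return a [KmerCounts-class] object.
#' @examples
#' set.seed(1)
#' g <- generateGenome(20000)
#' db <- buildKmerDatabase(g, k = 25)
#' reads <- simulateReads(g, depth = 0.5)
#' counts <- countReads(reads, db)
#' counts
#' @export
countSample <- function(files, db) {
  stopifnot(is(db, "KmerDatabase"), is.character(files), length(files) >= 1)
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("no such file: '", missing[1], "'")
  pooled <- NULL
  for (f in files) {
    reads <- .readFastq(f)
    cc <- .newCounts(db, cpp_count_reads(.dbLookup(db), unname(reads)), f)
    pooled <- if (is.null(pooled)) cc else mergeCounts(pooled, cc)
  }
  pooled
}

# strict 4-lines-per-record FASTQ reader (plain or gzip): a truncated file,
# a missing @/+ marker, or a sequence/quality length mismatch is a format
# error naming the file and record index. Missing final newline is tolerated.
.readFastq <- function(f) {
  con <- if (.isGz(f)) gzfile(f, "rt") else file(f, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(character(0))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ '", f, "': truncated record at read ",
         length(lines) %/% 4 + 1, call. = FALSE)
  idx <- seq.int(1L, length(lines), by = 4L)
  bad <- which(!startsWith(lines[idx], "@") | !startsWith(lines[idx + 2L], "+"))
  if (length(bad))
    stop("malformed FASTQ '", f, "': bad record structure at read ", bad[1],
         call. = FALSE)
  seqs <- lines[idx + 1L]
  mm <- which(nchar(seqs) != nchar(lines[idx + 3L]))
  if (length(mm))
    stop("malformed FASTQ '", f, "': sequence/quality length mismatch at read ",
         mm[1], call. = FALSE)
  seqs
}

#' @rdname countSample
#' @export
countReads <- function(reads, db) {
  stopifnot(is(db, "KmerDatabase"))
  .newCounts(db, cpp_count_reads(.dbLookup(db), unname(as.character(reads))),
             "<in-memory>")
}

#' Merge counts from disjoint inputs
#'
#' Field-wise addition of two [KmerCounts-class] objects taken against the
#' same database (checked by fingerprint); source file lists are concatenated.
#' Counting a file equals counting its parts and merging, which enables
#' chunked counting and replicate pooling.
#'
#' @param a,b [KmerCounts-class] objects from the same database.
#' @return the merged [KmerCounts-class].
#' @export
mergeCounts <- function(a, b) {
  stopifnot(is(a, "KmerCounts"), is(b, "KmerCounts"))
  if (!identical(a@dbHash, b@dbHash))
    stop("cannot merge counts taken against different databases")
  new("KmerCounts",
      tagCounts = a@tagCounts + b@tagCounts,
      errCounts = a@errCounts + b@errCounts,
      nNucl = a@nNucl + b@nNucl,
      nKmer = a@nKmer + b@nKmer,
      nReads = a@nReads + b@nReads,
      sourceFiles = c(a@sourceFiles, b@sourceFiles),
      dbHash = a@dbHash)
}

#' @rdname KmerCounts-class
#' @param x,object a `KmerCounts`.
#' @export
setMethod("tagCounts", "KmerCounts", function(x) x@tagCounts)

#' @rdname KmerCounts-class
#' @export
setMethod("errorCounts", "KmerCounts", function(x) x@errCounts)

#' @rdname KmerCounts-class
#' @export
setMethod("nNucl", "KmerCounts", function(x) x@nNucl)

#' @rdname KmerCounts-class
#' @export
setMethod("nKmer", "KmerCounts", function(x) x@nKmer)

#' @rdname KmerCounts-class
#' @export
setMethod("nReads", "KmerCounts", function(x) x@nReads)

setMethod("show", "KmerCounts", function(object) {
  cat("KmerCounts\n")
  cat("  reads:        ", format(object@nReads, big.mark = ","), "\n", sep = "")
  cat("  n_nucl:       ", format(object@nNucl, big.mark = ","), "\n", sep = "")
  cat("  n_kmer:       ", format(object@nKmer, big.mark = ","), "\n", sep = "")
  cat("  tag hits:     ", format(sum(object@tagCounts), big.mark = ","),
      " over ", length(object@tagCounts), " tag k-mers\n", sep = "")
  cat("  error hits:   ", format(sum(object@errCounts), big.mark = ","),
      " over ", length(object@errCounts), " error k-mers\n", sep = "")
  cat("  sources:      ", paste(utils::head(object@sourceFiles, 3), collapse = ", "),
      if (length(object@sourceFiles) > 3) ", ..." else "", "\n", sep = "")
})

#' Read and write count tables
#'
#' Counts are stored as TSV: header lines `#kmerdepth-counts v1`, `#k=`,
#' `#db=<fingerprint>`, `#n_nucl=`, `#n_kmer=`, `#n_reads=`, `#source=`,
#' then rows `<kmer> <type:tag|err> <count>`. Reading requires the database
#' the counts were taken against (the row order and fingerprint are checked).
#'
#' @param counts a [KmerCounts-class].
#' @param path file path (`.gz` for gzip).
#' @param db the [KmerDatabase-class] the counts belong to.
#' @return `writeCounts()`: `path`, invisibly; `readCounts()`: a
#'   [KmerCounts-class].
#' @export
writeCounts <- function(counts, path) {
  stopifnot(is(counts, "KmerCounts"))
  con <- if (.isGz(path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("#kmerdepth-counts v1",
               paste0("#db=", counts@dbHash),
               sprintf("#n_nucl=%.0f", counts@nNucl),
               sprintf("#n_kmer=%.0f", counts@nKmer),
               sprintf("#n_reads=%.0f", counts@nReads),
               paste0("#source=", paste(counts@sourceFiles, collapse = ","))),
             con)
  writeLines(c(paste(names(counts@tagCounts), "tag",
                     format(counts@tagCounts, scientific = FALSE, trim = TRUE),
                     sep = "\t"),
               paste(names(counts@errCounts), "err",
                     format(counts@errCounts, scientific = FALSE, trim = TRUE),
                     sep = "\t")),
             con)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path, db) {
  stopifnot(is(db, "KmerDatabase"))
  if (!file.exists(path)) stop("no such file: '", path, "'")
  con <- if (.isGz(path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con)
  close(con)
  if (!length(lines) || lines[1] != "#kmerdepth-counts v1")
    stop("'", path, "' is not a kmerdepth counts file")
  hdr <- lines[startsWith(lines, "#")]
  getH <- function(key) {
    v <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (!length(v)) stop("missing counts header field '", key, "'")
    sub(paste0("^#", key, "="), "", v[1])
  }
  if (getH("db") != .dbHash(db))
    stop("counts file was produced against a different database")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed counts row")
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  tc <- as.numeric(m[m[, 2] == "tag", 3])
  ec <- as.numeric(m[m[, 2] == "err", 3])
  if (!identical(m[m[, 2] == "tag", 1], db@tags$kmer) ||
      !identical(m[m[, 2] == "err", 1], db@errors$kmer))
    stop("counts file k-mers do not match the database")
  names(tc) <- db@tags$kmer
  names(ec) <- db@errors$kmer
  new("KmerCounts", tagCounts = tc, errCounts = ec,
      nNucl = as.numeric(getH("n_nucl")), nKmer = as.numeric(getH("n_kmer")),
      nReads = as.numeric(getH("n_reads")),
      sourceFiles = strsplit(getH("source"), ",", fixed = TRUE)[[1]],
      dbHash = .dbHash(db))
}
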