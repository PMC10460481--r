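#' Read and write k-mer databases as TSV
#'
#' The on-disk format is a plain TSV with three header lines
#' (`#kmerdepth-db v1`, `#k=<int>`, `#provenance=<json>`) followed by one row
#' per k-mer:
#' `<kmer> <type:tag|err> <record> <position> <window_1mb> <parent> <mm_pos> <mm_base>`,
#' tab-separated, with `.` for fields that do not apply. K-mer strings are
#' written in canonical orientation; positions are 0-based. The round trip is
#' lossless (ordering, annotations, provenance).
#'
#' @param db a [KmerDatabase-class].
#' @param path file path (a `.gz` suffix triggers gzip compression).
#' @return `writeKmerDatabase()` returns `path` invisibly;
#'   `readKmerDatabase()` returns a [KmerDatabase-class].
#' @export
writeKmerDatabase <- function(db, path) {
  stopifnot(is(db, "KmerDatabase"))
  con <- if (.isGz(path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("#kmerdepth-db v1",
               paste0("#k=", db@k),
               paste0("#provenance=", as.character(jsonlite::toJSON(
                 db@provenance, auto_unbox = TRUE, null = "null", digits = NA)))),
             con)
  tg <- db@tags
  er <- db@errors
  rows <- character(0)
  if (nrow(tg))
    rows <- c(rows, paste(tg$kmer, "tag", tg$record, tg$position, tg$window_1mb,
                          ".", ".", ".", sep = "\t"))
  if (nrow(er))
    rows <- c(rows, paste(er$kmer, "err", ".", ".", ".",
                          er$parent, er$mm_pos, er$mm_base, sep = "\t"))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname writeKmerDatabase
#' @export
readKmerDatabase <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  con <- if (.isGz(path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con)
  close(con)
  if (length(lines) < 3 || lines[1] != "#kmerdepth-db v1")
    stop("'", path, "' is not a kmerdepth database (missing '#kmerdepth-db v1' header)")
  if (!startsWith(lines[2], "#k="))
    stop("malformed database header (line 2): expected '#k=<int>'")
  k <- suppressWarnings(as.integer(sub("^#k=", "", lines[2])))
  if (is.na(k)) stop("malformed database header (line 2): unparsable k")
  prov <- list()
  if (startsWith(lines[3], "#provenance=")) {
    prov <- tryCatch(
      jsonlite::fromJSON(sub("^#provenance=", "", lines[3]), simplifyVector = TRUE),
      error = function(e) list(raw = sub("^#provenance=", "", lines[3])))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  lineNo <- which(!startsWith(lines, "#") & nzchar(lines))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 8L)
  if (length(bad))
    stop("malformed database row at line ", lineNo[bad[1]],
         ": expected 8 tab-separated fields, got ", lengths(parts)[bad[1]])
  m <- matrix(unlist(parts), ncol = 8, byrow = TRUE)
  type <- m[, 2]
  if (!all(type %in% c("tag", "err")))
    stop("malformed database row at line ",
         lineNo[which(!type %in% c("tag", "err"))[1]], ": unknown type")
  isTag <- type == "tag"
  dup <- which(duplicated(m[, 1]))
  if (length(dup))
    stop("duplicated k-mer code at line ", lineNo[dup[1]], ": ", m[dup[1], 1])
  tags <- data.frame(kmer = m[isTag, 1], record = m[isTag, 3],
                     position = as.integer(m[isTag, 4]),
                     window_1mb = as.integer(m[isTag, 5]),
                     stringsAsFactors = FALSE)
  errs <- data.frame(kmer = m[!isTag, 1], parent = m[!isTag, 6],
                     mm_pos = as.integer(m[!isTag, 7]),
                     mm_base = m[!isTag, 8],
                     stringsAsFactors = FALSE)
  if (nrow(tags) && (anyNA(tags$position) || anyNA(tags$window_1mb)))
    stop("malformed tag row: non-integer position/window field")
  if (nrow(errs) && anyNA(errs$mm_pos))
    stop("malformed err row: non-integer mm_pos field")
  db <- new("KmerDatabase", k = k, tags = tags, errors = errs,
            provenance = as.list(prov), cache = new.env(parent = emptyenv()))
  db
}
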