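## internal helpers

# run `code` under a temporary RNG state seeded with `seed`; NULL seed means
# "use the caller's RNG stream as-is"
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.looksLikeSequence <- function(x) {
  all(grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv.-]*$", x)) && !any(file.exists(x))
}

# coerce FASTA path(s) / XStringSet / character to a named character vector of
# sequences; names are the first whitespace-delimited token of each header
.asSequences <- function(x, what = "sequence") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq", seq_along(out))
    names(out) <- sub("\\s.*$", "", nm)
    return(out)
  }
  if (methods::is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq1"
    return(out)
  }
  if (is.character(x) && length(x) >= 1) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) return(x)
    if (.looksLikeSequence(x)) {
      names(x) <- paste0("seq", seq_along(x))
      return(x)
    }
    missing <- x[!file.exists(x)]
    if (length(missing))
      stop("cannot read ", what, ": no such file: '", missing[1], "'", call. = FALSE)
    sets <- lapply(x, function(f) {
      ss <- tryCatch(Biostrings::readDNAStringSet(f),
                     error = function(e) stop("cannot read FASTA '", f, "': ",
                                              conditionMessage(e), call. = FALSE))
      if (length(ss) == 0) stop("empty FASTA file: '", f, "'", call. = FALSE)
      ss
    })
    set <- do.call(c, sets)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  stop("cannot interpret ", what, ": supply FASTA path(s), an XStringSet, ",
       "or a (named) character vector of sequences", call. = FALSE)
}

.sourceLabel <- function(x) {
  if (is.character(x) && length(x) && all(file.exists(x))) return(paste(x, collapse = ","))
  paste0("<in-memory:", class(x)[1], ">")
}

.isGz <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)
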