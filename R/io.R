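#' Read a string collection from FASTA, FASTQ or raw text
#'
#' FASTA and FASTQ are parsed with Biostrings (multi-line sequences joined,
#' headers become ids, qualities discarded); raw text yields one string per
#' line with a final newline optional.  Gzip input is decompressed
#' transparently when `gzipped` is `TRUE` or the path ends in `.gz`.
#' In text mode, lines containing literal `#` or `$` are rejected because
#' those bytes render the internal end-marker and separator in text output.
#'
#' @param source Path to the input file.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`, `"text"`.  `"auto"`
#'   infers from the extension (`.fa`/`.fasta`/`.fna` for FASTA,
#'   `.fq`/`.fastq` for FASTQ, anything else text), stripping `.gz` first.
#' @param gzipped Logical or `NA`; `NA` means infer from a `.gz` suffix.
#' @return A [string_collection()].
#' @export
read_collection <- function(source, format = c("auto", "fasta", "fastq", "text"),
                            gzipped = NA) {
  format <- match.arg(format)
  if (!file.exists(source)) stop(sprintf("cannot read input: %s", source))
  gz <- if (is.na(gzipped)) grepl("\\.gz$", source) else isTRUE(gzipped)
  if (format == "auto") {
    base <- sub("\\.gz$", "", source)
    ext <- tolower(sub(".*\\.", "", basename(base)))
    format <- if (ext %in% c("fa", "fasta", "fna")) "fasta"
              else if (ext %in% c("fq", "fastq")) "fastq"
              else "text"
  }
  if (format %in% c("fasta", "fastq")) {
    if (format == "fastq") {
      con <- if (gz) gzfile(source, "rt") else file(source, "rt")
      nlines <- length(suppressWarnings(readLines(con)))
      close(con)
      if (nlines %% 4L != 0L) {
        stop(sprintf("malformed fastq input (%s): %d lines, not a multiple of 4",
                     source, nlines))
      }
    }
    x <- tryCatch(
      Biostrings::readBStringSet(source, format = format),
      error = function(e) stop(sprintf("malformed %s input (%s): %s",
                                       format, source, conditionMessage(e)))
    )
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    coll <- string_collection(ids, unname(as.character(x)))
  } else {
    con <- if (gz) gzfile(source, "rt") else file(source, "rt")
    on.exit(close(con))
    lines <- suppressWarnings(readLines(con))  # final newline optional
    if (any(grepl("[#$]", lines, fixed = FALSE))) {
      stop("text input contains literal '#' or '$', which collide with the rendered sentinels")
    }
    coll <- string_collection(sprintf("line%d", seq_along(lines)), lines)
  }
  coll
}

#' Write a string collection to FASTA, FASTQ or raw text
#'
#' The on-disk complement of [read_collection()], used mainly to materialize
#' synthetic fixtures.  FASTQ qualities are written as a constant placeholder
#' (`I`) since the index structures are over sequences only.
#'
#' @param coll A [string_collection()].
#' @param path Output path.
#' @param format `"fasta"`, `"fastq"` or `"text"`.
#' @param gzipped Compress the output with gzip.
#' @return `path`, invisibly.
#' @export
write_collection <- function(coll, path, format = c("fasta", "fastq", "text"),
                             gzipped = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(coll, "string_collection"))
  con <- if (gzipped) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", coll$ids), coll$seqs)),
    fastq = as.vector(rbind(paste0("@", coll$ids), coll$seqs, "+",
                            vapply(coll$lengths,
                                   function(n) strrep("I", n), ""))),
    text = coll$seqs
  )
  writeLines(lines, con)
  invisible(path)
}

.check_width <- function(width) {
  if (!width %in% c(4, 8)) stop("width must be 4 or 8 bytes")
  as.integer(width)
}

#' Write an integer array as headerless little-endian binary
#'
#' Each value is stored in `width` bytes (4 or 8), least significant byte
#' first, with no header or padding; the file size is exactly
#' `length(values) * width`.  Values are non-negative and must fit in
#' `2^(8 * width)`; above `2^53` only values exactly representable as doubles
#' survive the trip (R has no native 64-bit integer).
#'
#' @param values Numeric vector of non-negative integers.
#' @param width Bytes per value: 4 or 8.
#' @param sink Output path.
#' @return Number of bytes written.
#' @export
write_int_array <- function(values, width = 4, sink) {
  width <- .check_width(width)
  values <- as.numeric(values)
  bad <- which(values < 0 | values != floor(values) | values >= 2^(8 * width))
  if (length(bad)) {
    stop(sprintf("value at index %d does not fit in %d bytes", bad[1L] - 1L,
                 width))
  }
  n <- length(values)
  bytes <- raw(n * width)
  if (n) {
    for (k in seq_len(width) - 1L) {
      bytes[seq.int(k + 1L, by = width, length.out = n)] <-
        as.raw((values %/% 256^k) %% 256)
    }
  }
  writeBin(bytes, sink)
  n * width
}

#' Read a headerless little-endian integer array
#'
#' Exact inverse of [write_int_array()]: the file size must be divisible by
#' `width`.
#'
#' @param source Input path.
#' @param width Bytes per value: 4 or 8.
#' @return Numeric vector of non-negative integer values.
#' @export
read_int_array <- function(source, width = 4) {
  width <- .check_width(width)
  size <- file.info(source)$size
  if (is.na(size)) stop(sprintf("cannot read array file: %s", source))
  if (size %% width != 0) {
    stop(sprintf("file size %d is not divisible by width %d", size, width))
  }
  bytes <- readBin(source, "raw", n = size)
  n <- size %/% width
  if (n == 0) return(numeric(0))
  m <- matrix(as.numeric(bytes), nrow = width)
  as.vector(256^(seq_len(width) - 1L) %*% m)
}

#' Write a human-readable dump of the index arrays
#'
#' One header line, then one tab-separated line per row i with the requested
#' columns among `i`, `SA[i]`, `DA[i]`, `LCP[i]`, `BWT[i]` (rendered with
#' literal `#`/`$`) and the suffix `T[SA[i]..]` truncated to
#' `max_suffix_chars` characters.
#'
#' @param ct A `concat_text`.
#' @param sa Suffix array (required).
#' @param lcp,da,bwt Optional arrays; omitted columns are dropped.
#' @param sink Output path.
#' @param max_suffix_chars Truncation length for the suffix column; 0 drops
#'   the column.
#' @return `sink`, invisibly.
#' @export
write_txt_dump <- function(ct, sa, lcp = NULL, da = NULL, bwt = NULL,
                           sink, max_suffix_chars = 60L) {
  stopifnot(inherits(ct, "concat_text"))
  validate_sa(ct, sa)
  sa <- as.integer(sa)
  N <- ct$N
  cols <- list(i = seq_len(N) - 1L, SA = sa)
  if (!is.null(da)) cols$DA <- as.integer(da)
  if (!is.null(lcp)) cols$LCP <- as.integer(lcp)
  if (!is.null(bwt)) {
    cols$BWT <- vapply(as.integer(bwt), function(cc) render_bwt(cc), "")
  }
  if (max_suffix_chars > 0L) {
    rendered <- render_bwt(ct$codes)  # full text with literal sentinels
    cols$suffix <- substring(rendered, sa + 1L, pmin(N, sa + max_suffix_chars))
  }
  lines <- c(paste(names(cols), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, sink)
  invisible(sink)
}
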