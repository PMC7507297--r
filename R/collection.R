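#' Create a string collection
#'
#' A string collection is an ordered list of `d >= 1` byte strings with
#' identifiers.  Bytes 0 and 1 are reserved for the internal end-marker and
#' separator codes and must not occur in any sequence; printable ASCII
#' (bytes >= 32) is always safe.
#'
#' @param ids Character vector of labels, one per string.
#' @param seqs Character vector of sequences (byte strings; empty strings are
#'   permitted).
#' @return An object of class `string_collection` with fields `ids`, `seqs`,
#'   `d` (string count) and `lengths` (per-string symbol counts).
#' @examples
#' string_collection(c("s1", "s2"), c("AB", "CA"))
#' @export
string_collection <- function(ids, seqs) {
  stopifnot(is.character(ids), is.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length")
  }
  structure(
    list(ids = ids, seqs = seqs, d = length(seqs),
         lengths = vapply(seqs, function(s) length(charToRaw(s)), 0L,
                          USE.NAMES = FALSE)),
    class = "string_collection"
  )
}

#' @export
print.string_collection <- function(x, ...) {
  cat(sprintf("string_collection: d = %d, total symbols = %d\n",
              x$d, sum(x$lengths)))
  invisible(x)
}

#' Encode a collection as a separator-delimited concatenation
#'
#' Concatenates the `d` strings as `T = T1 $ T2 $ ... Td $ #` where `$` is a
#' per-string separator (internal code 1) and `#` the end-marker (code 0).
#' Content bytes are kept unchanged as codes, so all content codes are >= 2.
#' The end-marker is the smallest symbol, separators the next smallest, and
#' separator occurrences compare among themselves by text position, which is
#' what ranks equal suffixes of different strings by string number.
#'
#' @param coll A [string_collection()].
#' @return An object of class `concat_text` with fields:
#'   \describe{
#'     \item{codes}{integer vector of `N` symbol codes, `codes[N] == 0`;}
#'     \item{N}{total length `sum(n_i + 1) + 1`;}
#'     \item{d}{string count;}
#'     \item{sigma}{alphabet size (max code + 1);}
#'     \item{starts}{`d + 1` global 0-based start positions — one per string
#'       plus `N - 1` for the end-marker pseudo-string `d + 1`;}
#'     \item{sep_positions}{the `d` separator positions, strictly increasing.}
#'   }
#'   All coordinates are 0-based.
#' @examples
#' encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' @export
encode_collection <- function(coll) {
  stopifnot(inherits(coll, "string_collection"))
  if (coll$d == 0) stop("empty collection: d = 0, nothing to encode")
  byte_list <- lapply(coll$seqs, function(s) as.integer(charToRaw(s)))
  bad <- which(vapply(byte_list, function(b) any(b < 2L), FALSE))
  if (length(bad)) {
    stop(sprintf("reserved byte (< 2) in input string %d: codes 0 and 1 are internal",
                 bad[1]))
  }
  codes <- c(unlist(mapply(c, byte_list, 1L, SIMPLIFY = FALSE),
             use.names = FALSE), 0L)
  N <- length(codes)
  sep_positions <- which(codes == 1L) - 1L
  starts <- c(0L, sep_positions + 1L)  # starts[d + 1] == N - 1, the end-marker
  structure(
    list(codes = codes, N = N, d = coll$d, sigma = max(codes) + 1L,
         starts = starts, sep_positions = sep_positions),
    class = "concat_text"
  )
}

#' @export
print.concat_text <- function(x, ...) {
  cat(sprintf("concat_text: N = %d, d = %d, sigma = %d\n", x$N, x$d, x$sigma))
  invisible(x)
}

#' Decode the content of a concatenated text
#'
#' Drops the internal codes 0 and 1 and converts the remaining codes back to
#' the original concatenated sequence bytes, in order.
#'
#' @param ct A `concat_text`.
#' @return A single character string.
#' @export
decode_content <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  keep <- ct$codes[ct$codes >= 2L]
  if (!length(keep)) return("")
  rawToChar(as.raw(keep))
}

#' Convert global text positions to (string, offset) pairs
#'
#' String indices run `1..d + 1`: index `a <= d` owns positions
#' `starts[a] .. starts[a] + n_a` (the last of which is its separator, at
#' local offset `n_a`), and the end-marker at position `N - 1` is pseudo-string
#' `d + 1` at offset 0.
#'
#' @param ct A `concat_text`.
#' @param pos Integer vector of global 0-based positions in `[0, N - 1]`.
#' @return A list with integer vectors `a` (string index) and `b` (0-based
#'   local offset), each the length of `pos`.
#' @examples
#' ct <- encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' global_to_local(ct, 4L)  # a = 2, b = 1
#' @export
global_to_local <- function(ct, pos) {
  stopifnot(inherits(ct, "concat_text"))
  pos <- as.integer(pos)
  if (any(pos < 0L | pos > ct$N - 1L)) {
    stop(sprintf("position out of range [0, %d]", ct$N - 1L))
  }
  a <- findInterval(pos, ct$starts)
  list(a = a, b = pos - ct$starts[a])
}

#' Convert (string, offset) pairs to global text positions
#'
#' Exact inverse of [global_to_local()] on its range: `1 <= a <= d + 1` and
#' `0 <= b <= n_a`, where `b == n_a` addresses string `a`'s separator and
#' `(d + 1, 0)` the end-marker.
#'
#' @param ct A `concat_text`.
#' @param a Integer vector of string indices.
#' @param b Integer vector of local 0-based offsets.
#' @return Integer vector of global positions.
#' @export
local_to_global <- function(ct, a, b) {
  stopifnot(inherits(ct, "concat_text"))
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("`a` and `b` must have the same length")
  if (any(a < 1L | a > ct$d + 1L)) {
    stop(sprintf("string index out of range [1, %d]", ct$d + 1L))
  }
  # n_a: distance from each start to the separator; 0 for the end-marker.
  n_a <- c(ct$sep_positions - ct$starts[seq_len(ct$d)], 0L)[a]
  if (any(b < 0L | b > n_a)) stop("local offset out of range [0, n_a]")
  ct$starts[a] + b
}
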