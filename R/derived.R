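#' Burrows-Wheeler transform from the suffix array
#'
#' `bwt[i] = T[(sa[i] - 1) mod N]`: the symbol preceding the i-th smallest
#' suffix, with the end-marker wrapping to the last position.  The result is a
#' permutation of the text's symbol multiset.
#'
#' @param ct A `concat_text`.
#' @param sa Suffix array of `ct`.
#' @return Integer vector of `N` symbol codes with class `bwt_codes`.
#' @examples
#' ct <- encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' render_bwt(bwt_from_sa(ct, gsaca_k(ct)))  # "$BAC#A$"
#' @export
bwt_from_sa <- function(ct, sa) {
  stopifnot(inherits(ct, "concat_text"))
  validate_sa(ct, sa)
  structure(ct$codes[((as.integer(sa) - 1L) %% ct$N) + 1L], class = "bwt_codes")
}

#' Render BWT codes as text
#'
#' Code 0 becomes the literal `#`, code 1 the literal `$`, and every content
#' code its own byte.  Inputs read in text mode are rejected if they contain
#' literal `#` or `$`, so the rendering is unambiguous for them; FASTA/FASTQ
#' sequences never contain these characters.
#'
#' @param bwt A `bwt_codes` vector (or any internal code vector).
#' @return A single character string of length `N`.
#' @export
render_bwt <- function(bwt) {
  codes <- as.integer(bwt)
  codes[codes == 0L] <- 35L  # '#'
  codes[codes == 1L] <- 36L  # '$'
  rawToChar(as.raw(codes))
}

#' Parse rendered BWT bytes back to internal codes
#'
#' Inverse of [render_bwt()]: `#` to code 0, `$` to code 1.
#'
#' @param txt A character string (or raw vector) of rendered BWT bytes.
#' @return A `bwt_codes` integer vector.
#' @export
parse_rendered_bwt <- function(txt) {
  codes <- if (is.raw(txt)) as.integer(txt) else as.integer(charToRaw(txt))
  codes[codes == 35L] <- 0L
  codes[codes == 36L] <- 1L
  structure(codes, class = "bwt_codes")
}

#' Invert a multi-string BWT to the string multiset
#'
#' Walks the stable LF mapping (equal symbols keep their relative order
#' between the first and last columns) starting from the row whose first
#' symbol is the end-marker, emitting preceding symbols and splitting at
#' separators.  Because all separator occurrences are treated as one symbol,
#' the stable mapping may decompose into several cycles; every cycle contains
#' at least one separator row (content links are exact, and walking back
#' through any string reaches its leading separator), so the walk is restarted
#' from each unvisited separator row.  The emitted segments are the d original
#' strings plus one empty segment preceding the end-marker, which is dropped.
#' The recovered multiset equals the input multiset; the association of
#' strings to separators (string order) is not guaranteed.
#'
#' @param bwt A `bwt_codes` vector containing exactly one code 0 and `d`
#'   codes 1.
#' @param d The number of strings in the collection.
#' @return Character vector of the `d` recovered strings, sorted.
#' @export
invert_bwt <- function(bwt, d) {
  codes <- as.integer(bwt)
  N <- length(codes)
  if (sum(codes == 0L) != 1L) stop("malformed BWT: need exactly one end-marker")
  if (sum(codes == 1L) != d) {
    stop(sprintf("malformed BWT: expected %d separators, found %d",
                 d, sum(codes == 1L)))
  }
  cnt <- tabulate(codes + 1L, max(codes) + 1L)
  C <- cumsum(c(0L, cnt))            # C[c + 1] = count of symbols < c
  occ <- stats::ave(seq_len(N), codes, FUN = seq_along) - 1L
  LF <- C[codes + 1L] + occ          # 0-based target rows
  boundary <- codes < 2L

  visited <- logical(N)
  segments <- list()
  # Row 0 has first-column symbol '#'; its BWT symbol is the last separator,
  # so it always qualifies as a boundary-first start.
  starts <- unique(c(0L, which(boundary) - 1L))
  for (s0 in starts) {
    if (visited[s0 + 1L] || !boundary[s0 + 1L]) next
    i <- s0
    buf <- integer(0)
    first <- TRUE
    repeat {
      visited[i + 1L] <- TRUE
      cc <- codes[i + 1L]
      if (cc < 2L) {
        if (!first) segments[[length(segments) + 1L]] <- rev(buf)
        buf <- integer(0)
        first <- FALSE
      } else {
        buf <- c(buf, cc)
      }
      i <- LF[i + 1L]
      if (i == s0) break
    }
    segments[[length(segments) + 1L]] <- rev(buf)  # string ending at the
  }                                                # cycle's first boundary
  if (!all(visited)) stop("malformed BWT: LF cycles without separators")
  strs <- vapply(segments, function(s) {
    if (length(s)) rawToChar(as.raw(s)) else ""
  }, "")
  empty <- which(strs == "")
  if (!length(empty)) stop("malformed BWT: missing the end-marker's empty segment")
  sort(strs[-empty[1L]])
}

#' Separator-marking bitvector with constant-time rank
#'
#' `bits[i] = 1` iff `T[i]` is a separator (code 1).  The rank directory is a
#' full prefix-count table, so [rank1()] is a single vectorized lookup.
#'
#' @param ct A `concat_text`.
#' @return An object of class `rank_bitvector` with fields `bits` and `cum`.
#' @export
build_separator_bitvector <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  bits <- as.integer(ct$codes == 1L)
  structure(list(bits = bits, cum = cumsum(bits), N = ct$N),
            class = "rank_bitvector")
}

#' Number of separator bits strictly before a position
#'
#' `rank1(p)` counts ones among `bits[0 .. p-1]` — exclusive of `p` itself,
#' for `0 <= p <= N`.  Exclusivity is forced by the document-array identity:
#' `DA[0] = rank1(N - 1) + 1 = d + 1` must not count a separator at `N - 1`
#' (there is none, but inclusive rank would miscount every separator row).
#'
#' @param rb A `rank_bitvector`.
#' @param p Integer vector of positions in `[0, N]`.
#' @return Integer vector of counts.
#' @export
rank1 <- function(rb, p) {
  stopifnot(inherits(rb, "rank_bitvector"))
  p <- as.integer(p)
  if (any(p < 0L | p > rb$N)) stop(sprintf("rank position out of [0, %d]", rb$N))
  c(0L, rb$cum)[p + 1L]
}

#' Document array: owning string of each suffix
#'
#' `da[i]` is the index of the string owning suffix `sa[i]` (a separator
#' belongs to the string it terminates; the end-marker to pseudo-string
#' `d + 1`, so `da[0] = d + 1` always).  `mode = "direct"` locates each
#' position among the string start offsets; `mode = "light"` uses the
#' separator bitvector identity `da[i] = rank1(sa[i]) + 1`, trading a little
#' speed for not materializing the start table.  Both modes return identical
#' arrays.
#'
#' @param ct A `concat_text`.
#' @param sa Suffix array of `ct`.
#' @param mode `"direct"` or `"light"`.
#' @return Integer vector of `N` string indices in `[1, d + 1]`.
#' @examples
#' ct <- encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' document_array(ct, gsaca_k(ct))  # 3 1 2 2 1 1 2
#' @export
document_array <- function(ct, sa, mode = c("direct", "light")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ct, "concat_text"))
  validate_sa(ct, sa)
  sa <- as.integer(sa)
  if (mode == "direct") {
    global_to_local(ct, sa)$a
  } else {
    rank1(build_separator_bitvector(ct), sa) + 1L
  }
}

#' Generalized suffix array from SA and DA
#'
#' Rewrites each global suffix position as a (string, offset) pair:
#' `docs[i] = da[i]` and `offs[i] = sa[i] - start(da[i])`.  Two equivalent
#' routes compute the start of string a: the separator-prefix route exploits
#' that `sa[1..d]` are the separator positions in string order, so
#' `start(a) = sa[a - 1] + 1` for a >= 2 (0-based SA indexing) and
#' `start(1) = 0`; the direct route reads the `starts` field of the text.
#' Both are computed and must agree; every pair round-trips through
#' [local_to_global()] to `sa[i]`.  Separator suffixes get `offs = n_a` and
#' the end-marker `(d + 1, 0)`, extending the per-string definition to all N
#' rows.
#'
#' @param ct A `concat_text`.
#' @param sa Suffix array of `ct`.
#' @param da Document array for `sa` (computed if missing).
#' @return A list with integer vectors `docs` and `offs`, class `gsa_pairs`.
#' @examples
#' ct <- encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' sa <- gsaca_k(ct)
#' gsa_from_sa_da(ct, sa, document_array(ct, sa))
#' @export
gsa_from_sa_da <- function(ct, sa, da = document_array(ct, sa)) {
  stopifnot(inherits(ct, "concat_text"))
  validate_sa(ct, sa)
  sa <- as.integer(sa)
  da <- as.integer(da)
  if (length(da) != ct$N || any(da < 1L | da > ct$d + 1L)) {
    stop("document array inconsistent with the text")
  }
  # Route 1: string starts read off the separator prefix of the SA itself.
  start_sep <- c(0L, sa[1L + seq_len(ct$d)] + 1L)  # start(a), a = 1..d+1
  offs <- sa - start_sep[da]
  # Route 2: starts field of the text.
  offs2 <- sa - ct$starts[da]
  if (any(offs != offs2)) {
    stop(sprintf("GSA route mismatch at i = %d", which(offs != offs2)[1L] - 1L))
  }
  n_a <- c(ct$sep_positions - ct$starts[seq_len(ct$d)], 0L)[da]
  bad <- which(offs < 0L | offs > n_a | ct$starts[da] + offs != sa)
  if (length(bad)) {
    stop(sprintf("GSA consistency violation at i = %d", bad[1L] - 1L))
  }
  stopifnot(local_to_global(ct, da, offs) == sa)
  structure(list(docs = da, offs = offs), class = "gsa_pairs")
}

#' @export
print.gsa_pairs <- function(x, ...) {
  cat(sprintf("gsa_pairs: %d (string, offset) entries\n", length(x$docs)))
  invisible(x)
}

#' Build every index array for a concatenated text
#'
#' Convenience wrapper running the full pipeline in memory: suffix array,
#' capped LCP, BWT, document array (requested mode), and GSA.
#'
#' @param ct A `concat_text`.
#' @param light Use the rank-bitvector document-array mode.
#' @return A list with elements `sa`, `lcp`, `bwt`, `da`, `gsa`.
#' @export
build_all_arrays <- function(ct, light = FALSE) {
  sa <- gsaca_k(ct)
  da <- document_array(ct, sa, mode = if (light) "light" else "direct")
  list(sa = sa,
       lcp = lcp_from_sa(ct, sa),
       bwt = bwt_from_sa(ct, sa),
       da = da,
       gsa = gsa_from_sa_da(ct, sa, da))
}
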