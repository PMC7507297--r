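#' Capped longest common prefix of two suffixes
#'
#' Returns the largest h such that the suffixes starting at `p` and `q` agree
#' on their first h symbols with every compared symbol a content code (>= 2).
#' Separator and end-marker occurrences never match anything — not even
#' themselves — so two suffixes both starting at separators have capped LCP 0
#' and no match ever crosses a string boundary.  This is exactly the plain LCP
#' after remapping every separator occurrence to a distinct symbol.
#'
#' @param ct A `concat_text`.
#' @param p,q Global 0-based positions in `[0, N - 1]`.
#' @return Integer match length in symbols.
#' @examples
#' ct <- encode_collection(string_collection(c("a", "b"), c("ANA", "ANANA")))
#' capped_lcp(ct, 0L, 4L)  # 3: "ANA" matches, then separator vs "N" stops
#' @export
capped_lcp <- function(ct, p, q) {
  stopifnot(inherits(ct, "concat_text"))
  p <- as.integer(p); q <- as.integer(q)
  stopifnot(p >= 0L, q >= 0L, p <= ct$N - 1L, q <= ct$N - 1L)
  codes <- ct$codes
  m <- min(ct$N - p, ct$N - q)
  a <- codes[p + seq_len(m)]
  b <- codes[q + seq_len(m)]
  bad <- which(a != b | a < 2L)
  if (length(bad)) bad[1L] - 1L else m
}

#' LCP array from text and suffix array
#'
#' Computes `lcp[i] = capped_lcp(sa[i], sa[i-1])` for i >= 1 (and `lcp[0] = 0`)
#' in O(N) with the Phi/permuted-LCP sweep of the Kasai algorithm, using the
#' capped matching predicate.  The sweep's h-decrement argument remains valid
#' because capping equals plain matching on the distinct-separator remapping,
#' whose suffix order is the one `sa` realizes.
#'
#' @param ct A `concat_text`.
#' @param sa Suffix array of `ct` in the rank-tie-breaking order.
#' @return Integer vector of `N` non-negative lengths.
#' @examples
#' ct <- encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' lcp_from_sa(ct, gsaca_k(ct))  # 0 0 0 0 1 0 0
#' @export
lcp_from_sa <- function(ct, sa) {
  stopifnot(inherits(ct, "concat_text"))
  validate_sa(ct, sa)
  cpp_lcp_phi(ct$codes, as.integer(sa))
}
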