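#' Suffix array construction in the rank-tie-breaking order
#'
#' Builds the suffix array of a separator-delimited concatenation by induced
#' sorting (the SA-IS/SACA-K family) in O(N) time.  The target order is
#' lexicographic under the augmented symbol comparison: end-marker < separator
#' < content codes, and two separator occurrences compare by text position, so
#' equal suffixes from different strings are ranked by string number.  The
#' construction sorts LMS substrings by induction, names them (any LMS
#' substring containing a separator receives a fresh name, issued in text
#' order, which realizes the positional tie-breaking), recurses on the reduced
#' string while names repeat, and finally induces the complete order with the
#' separator suffixes pinned at their positional ranks.
#'
#' @param ct A `concat_text` from [encode_collection()].
#' @return Integer vector of `N` global 0-based positions — a permutation of
#'   `0:(N-1)` with `sa[1] == N - 1` and the next `d` entries equal to the
#'   separator positions in increasing order.  The recursion depth used is
#'   attached as attribute `"recursion_depth"`.
#' @examples
#' ct <- encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
#' gsaca_k(ct)  # 6 2 5 4 0 1 3
#' @seealso [brute_force_sa()], [reference_sa()] for the test oracles.
#' @export
gsaca_k <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  res <- cpp_gsaca_k(ct$codes)
  structure(res$sa, recursion_depth = res$depth)
}

#' Remap a concatenated text so every separator is a distinct symbol
#'
#' The end-marker keeps code 0, the k-th separator occurrence becomes code k,
#' and every content code c becomes c + d.  Plain lexicographic suffix order
#' of the remapped text equals the rank-tie-breaking order of the original;
#' this is the semantic definition the construction is tested against.
#'
#' @param ct A `concat_text`.
#' @return Integer vector of remapped codes (alphabet `0 .. max`).
#' @export
remap_distinct_separators <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  codes <- ct$codes
  sep_rank <- cumsum(codes == 1L)
  out <- codes + ct$d
  out[codes == 1L] <- sep_rank[codes == 1L]
  out[codes == 0L] <- 0L
  out
}

#' Brute-force suffix array oracle
#'
#' Sorts all `N` suffixes by direct comparison under the augmented order,
#' realized by remapping every separator occurrence to a distinct ascending
#' code and lexicographically ordering the padded suffix matrix.  Quadratic
#' memory; intended as ground truth on small inputs.
#'
#' @param ct A `concat_text`.
#' @return Integer vector of `N` 0-based suffix start positions.
#' @export
brute_force_sa <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  codes <- remap_distinct_separators(ct)
  N <- ct$N
  if (N == 1L) return(0L)
  # m[i, k] = symbol k of suffix i (remapped), -1 past the end.  The end-marker
  # is a unique minimum so padding never decides a comparison.
  m <- matrix(-1L, nrow = N, ncol = N)
  for (i in seq_len(N)) m[i, seq_len(N - i + 1L)] <- codes[i:N]
  ord <- do.call(order, lapply(seq_len(N), function(k) m[, k]))
  ord - 1L
}

#' Plain SA-IS suffix array (reference implementation)
#'
#' Textbook induced sorting for a single string whose last symbol is a unique
#' smallest sentinel (code 0).  Pure R, used as an independent reference:
#' running it on [remap_distinct_separators()] output must reproduce
#' [gsaca_k()] exactly.
#'
#' @param codes Integer vector of symbol codes with `codes[length(codes)] == 0`
#'   occurring nowhere else.
#' @return Integer vector of 0-based suffix start positions.
#' @export
sais_plain <- function(codes) {
  s <- as.integer(codes)
  n <- length(s)
  stopifnot(n >= 1L, s[n] == 0L, sum(s == 0L) == 1L)
  sa <- .sais_rec(s, max(s) + 1L)
  sa
}

# Recursive worker: s is 0-based-coded, 1-based-indexed; returns 0-based SA.
.sais_rec <- function(s, K) {
  n <- length(s)
  if (n == 1L) return(0L)
  tS <- logical(n)
  tS[n] <- TRUE
  for (i in (n - 1L):1L) {
    tS[i] <- s[i] < s[i + 1L] || (s[i] == s[i + 1L] && tS[i + 1L])
  }
  isLMS <- c(FALSE, tS[-1L] & !tS[-n])
  lms <- which(isLMS)                      # 1-based text positions
  cnt <- tabulate(s + 1L, K)

  induce <- function(sa) {
    heads <- cumsum(cnt) - cnt + 1L
    for (i in seq_len(n)) {
      j <- sa[i]                           # 0-based or -1
      if (j > 0L && !tS[j]) {              # predecessor j-1 (0-based) = index j
        c1 <- s[j] + 1L
        sa[heads[c1]] <- j - 1L
        heads[c1] <- heads[c1] + 1L
      }
    }
    tails <- cumsum(cnt)
    for (i in n:1L) {
      j <- sa[i]
      if (j > 0L && tS[j]) {
        c1 <- s[j] + 1L
        sa[tails[c1]] <- j - 1L
        tails[c1] <- tails[c1] - 1L
      }
    }
    sa
  }

  # Phase A: seed LMS in text order at bucket tails, induce substring order.
  sa <- rep(-1L, n)
  tails <- cumsum(cnt)
  for (p in rev(lms)) {
    c1 <- s[p] + 1L
    sa[tails[c1]] <- p - 1L
    tails[c1] <- tails[c1] - 1L
  }
  sa <- induce(sa)

  # Name LMS substrings in sorted order.
  sorted <- sa[isLMS[sa + 1L]] + 1L        # 1-based LMS positions, sorted
  name <- integer(n)
  cur <- 0L
  prev <- sorted[1L]
  name[prev] <- 1L
  for (z in seq_along(sorted)[-1L]) {
    p <- sorted[z]
    diff <- FALSE
    k <- 0L
    repeat {
      if (p + k > n || prev + k > n) { diff <- TRUE; break }
      pe <- k > 0L && isLMS[p + k]
      qe <- k > 0L && isLMS[prev + k]
      if (pe && qe) break
      if (pe != qe || s[p + k] != s[prev + k]) { diff <- TRUE; break }
      k <- k + 1L
    }
    if (diff) { cur <- cur + 1L; prev <- p }
    name[p] <- cur + 1L
  }
  nlms <- length(lms)
  nnames <- cur + 1L

  if (nnames < nlms) {
    s1 <- name[lms] - 1L
    sa1 <- .sais_rec(s1, nnames)
    salms <- lms[sa1 + 1L]
  } else {
    salms <- integer(nlms)
    salms[name[lms]] <- lms
  }

  # Phase B: seed LMS suffixes in true order, induce the final array.
  sa <- rep(-1L, n)
  tails <- cumsum(cnt)
  for (p in rev(salms)) {
    c1 <- s[p] + 1L
    sa[tails[c1]] <- p - 1L
    tails[c1] <- tails[c1] - 1L
  }
  induce(sa)
}

#' Reference suffix array via distinct-separator remapping
#'
#' Runs plain SA-IS ([sais_plain()]) on the distinct-separator remapping of
#' the text.  By construction this is the rank-tie-breaking order; it serves
#' as a second, independent check on [gsaca_k()].
#'
#' @param ct A `concat_text`.
#' @return Integer vector of 0-based suffix start positions.
#' @export
reference_sa <- function(ct) {
  sais_plain(remap_distinct_separators(ct))
}

#' Classify text positions as L- or S-type
#'
#' Position `N - 1` is S; position i is S iff `T[i] < T[i+1]`, or
#' `T[i] == T[i+1]` and either both are separators (the earlier occurrence is
#' the smaller symbol) or position i + 1 is S.  LMS positions are S-positions
#' immediately preceded by an L-position.
#'
#' @param ct A `concat_text`.
#' @return A list with `types` (character vector of `"L"`/`"S"`, length `N`)
#'   and `lms` (increasing integer vector of 0-based LMS positions).
#' @export
classify_ls_types <- function(ct) {
  stopifnot(inherits(ct, "concat_text"))
  codes <- ct$codes
  N <- ct$N
  s <- logical(N)
  s[N] <- TRUE
  if (N >= 2L) {
    cur <- codes[-N]
    nxt <- codes[-1L]
    dec <- ifelse(cur < nxt, TRUE,
                  ifelse(cur > nxt, FALSE,
                         ifelse(cur == 1L, TRUE, NA)))
    s[-N] <- dec
    for (i in rev(which(is.na(s)))) s[i] <- s[i + 1L]
  }
  pred <- c(TRUE, s[-N])  # position 0 has no predecessor, never LMS
  list(types = ifelse(s, "S", "L"), lms = which(s & !pred) - 1L)
}

#' Complete a suffix array by one induction from seeded LMS positions
#'
#' Given the L/S type map and a partial array holding the correctly ordered
#' content LMS positions at their bucket tails (all other slots `NA`), runs
#' the two classical sweeps — left-to-right inducing L-suffixes from bucket
#' heads, right-to-left inducing S-suffixes from bucket tails.  The
#' end-marker and all separator positions are pinned beforehand at ranks
#' `0` and `1..d` (increasing text order) and are never overwritten: their
#' within-bucket order is positional, which ordinary induction cannot
#' reproduce.
#'
#' @param ct A `concat_text`.
#' @param types Output of [classify_ls_types()].
#' @param seeded Integer vector of length `N`: 0-based positions or `NA`.
#' @return Integer vector: the complete suffix array.
#' @export
induced_sort_pass <- function(ct, types, seeded) {
  stopifnot(inherits(ct, "concat_text"), length(seeded) == ct$N,
            length(types$types) == ct$N)
  sa <- cpp_induce(ct$codes, types$types == "S", as.integer(seeded))
  if (anyNA(sa) || any(sort.int(sa) != seq_len(ct$N) - 1L)) {
    stop("induction did not fill a permutation: bucket seeding is inconsistent")
  }
  sa
}

#' Validate a suffix array against its text
#'
#' Checks the structural invariants: a permutation of `0:(N-1)`, the
#' end-marker suffix first, then the separator positions in increasing order.
#'
#' @param ct A `concat_text`.
#' @param sa Integer vector of length `N`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_sa <- function(ct, sa) {
  if (length(sa) != ct$N || any(sort.int(as.integer(sa)) != seq_len(ct$N) - 1L)) {
    stop("suffix array is not a permutation of 0:(N-1)")
  }
  if (sa[1L] != ct$N - 1L) stop("sa[0] must be the end-marker position N-1")
  if (ct$d > 0L && any(sa[1L + seq_len(ct$d)] != ct$sep_positions)) {
    stop("sa[1..d] must equal the separator positions in increasing order")
  }
  invisible(TRUE)
}
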