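# Shared randomized corpus, computed once per test run and cached.
# Each entry: coll, ct, sa (construction), brute (pairwise-comparison oracle),
# ref (plain SA-IS on the distinct-separator remap), depth, lcp, lcp_brute.

.corpus_env <- new.env(parent = emptyenv())

corpus_results <- function() {
  if (is.null(.corpus_env$res)) {
    corpus <- oracle_corpus()
    .corpus_env$res <- lapply(corpus, function(x) {
      ct <- encode_collection(x$coll)
      sa <- gsaca_k(ct)
      lcp <- lcp_from_sa(ct, sa)
      list(coll = x$coll, ct = ct, sa = as.integer(sa),
           depth = attr(sa, "recursion_depth"),
           brute = brute_force_sa(ct), ref = reference_sa(ct),
           lcp = lcp,
           lcp_brute = c(0L, vapply(seq_len(ct$N)[-1L], function(i) {
             capped_lcp(ct, sa[i], sa[i - 1L])
           }, 0L)))
    })
  }
  .corpus_env$res
}

# The two-string worked collection used throughout the suite.
w1_text <- function() {
  encode_collection(string_collection(c("s1", "s2"), c("AB", "CA")))
}
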