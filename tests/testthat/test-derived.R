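test_that("BWT follows the preceding-symbol identity", {
  ct <- w1_text()
  sa <- gsaca_k(ct)
  bwt <- bwt_from_sa(ct, sa)
  expect_equal(as.integer(bwt), c(1L, 66L, 65L, 67L, 0L, 65L, 1L))
  expect_equal(render_bwt(bwt), "$BAC#A$")
  # wrap-around: the row holding suffix 0 carries the end-marker
  expect_equal(as.integer(bwt)[which(sa == 0L)], 0L)

  ct1 <- encode_collection(string_collection("a", "A"))
  expect_equal(render_bwt(bwt_from_sa(ct1, gsaca_k(ct1))), "$A#")
})

test_that("BWT conserves the symbol multiset and scatters back to the text", {
  for (r in corpus_results()[seq(1, 500, by = 9)]) {
    ct <- r$ct
    bwt <- bwt_from_sa(ct, r$sa)
    expect_equal(sort.int(as.integer(bwt)), sort.int(ct$codes))
    rebuilt <- integer(ct$N)
    rebuilt[((r$sa - 1L) %% ct$N) + 1L] <- as.integer(bwt)
    expect_equal(rebuilt, ct$codes)
  }
})

test_that("BWT inversion recovers the string multiset", {
  ct <- w1_text()
  expect_equal(invert_bwt(bwt_from_sa(ct, gsaca_k(ct)), 2L),
               sort(c("AB", "CA")))
  ct1 <- encode_collection(string_collection("a", "A"))
  expect_equal(invert_bwt(bwt_from_sa(ct1, gsaca_k(ct1)), 1L), "A")
  # a collection whose stable LF decomposes into several cycles
  ctc <- encode_collection(string_collection(c("a", "b"), c("B", "A")))
  expect_equal(invert_bwt(bwt_from_sa(ctc, gsaca_k(ctc)), 2L), c("A", "B"))
  expect_error(invert_bwt(structure(c(65L, 0L), class = "bwt_codes"), 2L),
               "malformed")

  for (r in corpus_results()[seq(2, 500, by = 5)]) {
    bwt <- bwt_from_sa(r$ct, r$sa)
    expect_equal(invert_bwt(bwt, r$ct$d), sort(r$coll$seqs))
  }
})

test_that("separator bitvector rank is exclusive and counts prefixes", {
  ct <- w1_text()
  rb <- build_separator_bitvector(ct)
  expect_equal(rb$bits, c(0L, 0L, 1L, 0L, 0L, 1L, 0L))
  expect_equal(rank1(rb, 0L), 0L)
  expect_equal(rank1(rb, 3L), 1L)
  expect_equal(rank1(rb, 7L), 2L)
  expect_equal(rank1(rb, 0:7), c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L))
  expect_error(rank1(rb, 8L), "out of")
})

test_that("document array: direct and light modes agree and da[0] = d + 1", {
  ct <- w1_text()
  sa <- gsaca_k(ct)
  expect_equal(document_array(ct, sa), c(3L, 1L, 2L, 2L, 1L, 1L, 2L))
  ct1 <- encode_collection(string_collection("a", "A"))
  expect_equal(document_array(ct1, gsaca_k(ct1)), c(2L, 1L, 1L))

  for (r in corpus_results()[seq(1, 500, by = 4)]) {
    da <- document_array(r$ct, r$sa, mode = "direct")
    expect_identical(document_array(r$ct, r$sa, mode = "light"), da)
    expect_equal(da[1L], r$ct$d + 1L)
  }
})

test_that("GSA pairs round-trip to global positions by either route", {
  ct <- w1_text()
  sa <- gsaca_k(ct)
  g <- gsa_from_sa_da(ct, sa)
  expect_equal(g$docs, c(3L, 1L, 2L, 2L, 1L, 1L, 2L))
  expect_equal(g$offs, c(0L, 2L, 2L, 1L, 0L, 1L, 0L))

  ct1 <- encode_collection(string_collection("a", "A"))
  g1 <- gsa_from_sa_da(ct1, gsaca_k(ct1))
  expect_equal(g1$docs, c(2L, 1L, 1L))
  expect_equal(g1$offs, c(0L, 1L, 0L))

  for (r in corpus_results()[seq(1, 500, by = 11)]) {
    g <- gsa_from_sa_da(r$ct, r$sa)   # internally cross-checks both routes
    expect_equal(local_to_global(r$ct, g$docs, g$offs), r$sa)
    # suffixes of the first string keep their global offset
    first <- g$docs == 1L
    expect_equal(g$offs[first], r$sa[first])
    # each separator's own suffix sits at offset n_a
    n_a <- r$ct$sep_positions - r$ct$starts[seq_len(r$ct$d)]
    sep_rows <- match(r$ct$sep_positions, r$sa)
    expect_equal(g$offs[sep_rows], n_a)
    expect_equal(g$docs[sep_rows], seq_len(r$ct$d))
  }
  expect_error(gsa_from_sa_da(ct, sa, da = rep(2L, 7L)), "consistency violation")
})
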