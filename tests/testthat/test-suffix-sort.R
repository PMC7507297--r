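test_that("brute-force oracle reproduces hand-enumerable suffix orders", {
  expect_equal(brute_force_sa(w1_text()), c(6L, 2L, 5L, 4L, 0L, 1L, 3L))
  expect_equal(brute_force_sa(encode_collection(string_collection("a", "A"))),
               c(2L, 1L, 0L))
  # two empty strings: end-marker, then the separators by position
  cte <- encode_collection(string_collection(c("a", "b"), c("", "")))
  expect_equal(cte$codes, c(1L, 1L, 0L))
  expect_equal(brute_force_sa(cte), c(2L, 0L, 1L))
})

test_that("L/S classification follows the augmented comparison", {
  ct1 <- encode_collection(string_collection("a", "A"))
  tm <- classify_ls_types(ct1)
  expect_equal(tm$types, c("L", "L", "S"))
  expect_equal(tm$lms, 2L)  # end-marker is S preceded by the L-type separator

  w1 <- classify_ls_types(w1_text())
  expect_equal(w1$types, c("S", "L", "S", "L", "L", "L", "S"))
  expect_equal(w1$lms, c(2L, 6L))

  ba <- classify_ls_types(encode_collection(string_collection("a", "BA")))
  expect_equal(ba$types, c("L", "L", "L", "S"))
  expect_equal(ba$lms, 3L)

  # adjacent separators (empty string): the earlier occurrence is smaller, so
  # a separator followed by a separator is S-type
  cte <- encode_collection(string_collection(c("a", "b"), c("", "G")))
  expect_equal(classify_ls_types(cte)$types, c("S", "L", "L", "S"))

  # every LMS position is a strict local minimum of the augmented order:
  # its suffix is smaller than both neighbours' suffixes
  for (r in corpus_results()[seq(1, 500, by = 25)]) {
    tm <- classify_ls_types(r$ct)
    rank <- integer(r$ct$N)
    rank[r$brute + 1L] <- seq_len(r$ct$N)
    for (p in tm$lms) {
      expect_lt(rank[p + 1L], rank[p])          # smaller than predecessor
      if (p < r$ct$N - 1L) expect_lt(rank[p + 1L], rank[p + 2L])
    }
  }
})

test_that("one induction from correctly seeded LMS completes the array", {
  seed_from <- function(ct, sa_true) {
    tm <- classify_ls_types(ct)
    lms <- tm$lms[ct$codes[tm$lms + 1L] >= 2L]  # content LMS only
    seeded <- rep(NA_integer_, ct$N)
    tails <- cumsum(tabulate(ct$codes + 1L, ct$sigma))
    for (p in rev(sa_true[sa_true %in% lms])) {
      c1 <- ct$codes[p + 1L] + 1L
      seeded[tails[c1]] <- p
      tails[c1] <- tails[c1] - 1L
    }
    list(types = tm, seeded = seeded)
  }
  ct <- w1_text()
  s <- seed_from(ct, brute_force_sa(ct))
  expect_equal(induced_sort_pass(ct, s$types, s$seeded),
               c(6L, 2L, 5L, 4L, 0L, 1L, 3L))

  ct1 <- encode_collection(string_collection("a", "A"))
  s1 <- seed_from(ct1, brute_force_sa(ct1))
  expect_equal(induced_sort_pass(ct1, s1$types, s1$seeded), c(2L, 1L, 0L))

  for (r in corpus_results()[seq(3, 500, by = 17)]) {
    s <- seed_from(r$ct, r$brute)
    expect_equal(induced_sort_pass(r$ct, s$types, s$seeded), r$brute)
  }
})

test_that("construction is deterministic and satisfies the SA invariants", {
  for (r in corpus_results()[seq(1, 500, by = 7)]) {
    ct <- r$ct
    sa <- r$sa
    expect_equal(sort.int(sa), seq_len(ct$N) - 1L)    # permutation
    expect_equal(sa[1L], ct$N - 1L)                   # end-marker first
    expect_equal(sa[1L + seq_len(ct$d)], ct$sep_positions)
    expect_true(validate_sa(ct, sa))
    expect_equal(as.integer(gsaca_k(ct)), sa)         # identical re-run
    expect_lte(r$depth, max(1, ceiling(log2(ct$N))))  # recursion halves
  }
})

test_that("deep recursion inputs still match the oracles", {
  # highly repetitive strings force many equal LMS names and real recursion
  coll <- string_collection(c("a", "b", "c"),
                            c(strrep("AB", 40), strrep("ABAB", 25), "ABA"))
  ct <- encode_collection(coll)
  sa <- gsaca_k(ct)
  expect_gt(attr(sa, "recursion_depth"), 1L)
  expect_equal(as.integer(sa), brute_force_sa(ct))
  expect_equal(as.integer(sa), reference_sa(ct))
})
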