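test_that("encoding concatenates with separators and end-marker", {
  ct <- w1_text()
  expect_equal(ct$codes, c(65L, 66L, 1L, 67L, 65L, 1L, 0L))
  expect_equal(ct$N, 7L)
  expect_equal(ct$d, 2L)
  expect_equal(ct$sigma, 68L)
  expect_equal(ct$starts, c(0L, 3L, 6L))
  expect_equal(ct$sep_positions, c(2L, 5L))

  ct1 <- encode_collection(string_collection("a", "A"))
  expect_equal(ct1$codes, c(65L, 1L, 0L))
  expect_equal(ct1$starts, c(0L, 2L))
  expect_equal(ct1$sep_positions, 1L)

  # an empty string contributes a lone separator
  cte <- encode_collection(string_collection(c("e", "g"), c("", "G")))
  expect_equal(cte$codes, c(1L, 71L, 1L, 0L))
  expect_equal(cte$N, 4L)
  expect_equal(cte$starts, c(0L, 1L, 3L))
})

test_that("encoding rejects reserved bytes and empty collections", {
  bad <- string_collection("x", rawToChar(as.raw(c(65L, 1L))))
  expect_error(encode_collection(bad), "reserved byte")
  empty <- structure(list(ids = character(0), seqs = character(0), d = 0L,
                          lengths = integer(0)), class = "string_collection")
  expect_error(encode_collection(empty), "empty collection")
})

test_that("global/local coordinate conversion matches the worked example", {
  ct <- w1_text()
  expect_equal(global_to_local(ct, 4L), list(a = 2L, b = 1L))
  expect_equal(global_to_local(ct, 6L), list(a = 3L, b = 0L))
  expect_equal(global_to_local(ct, 2L), list(a = 1L, b = 2L))
  expect_equal(local_to_global(ct, 1L, 0L), 0L)
  expect_equal(local_to_global(ct, 2L, 1L), 4L)
  expect_equal(local_to_global(ct, 2L, 2L), 5L)
  expect_error(global_to_local(ct, 7L), "out of range")
  expect_error(local_to_global(ct, 4L, 0L), "out of range")
  expect_error(local_to_global(ct, 2L, 3L), "out of range")
})

test_that("coordinate round trip and content conservation hold on the corpus", {
  for (r in corpus_results()[seq(1, 500, by = 10)]) {
    ct <- r$ct
    pos <- seq_len(ct$N) - 1L
    gl <- global_to_local(ct, pos)
    expect_equal(local_to_global(ct, gl$a, gl$b), pos)
    expect_identical(decode_content(ct), paste(r$coll$seqs, collapse = ""))
    # starts and separator positions mutually consistent
    expect_equal(ct$starts, c(0L, ct$sep_positions + 1L))
    expect_true(all(diff(ct$sep_positions) > 0L) || ct$d == 1L)
    expect_equal(ct$N, sum(r$coll$lengths) + ct$d + 1L)
  }
})
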