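test_that("fixture generation is deterministic and respects its spec", {
  spec <- fixture_spec(d = 4, alphabet = "dna4", min_len = 1, max_len = 40,
                       seed = 11)
  a <- generate_collection(spec)
  b <- generate_collection(spec)
  expect_identical(a$seqs, b$seqs)
  expect_true(all(a$lengths >= 1 & a$lengths <= 40))
  expect_true(all(strsplit(paste(a$seqs, collapse = ""), "")[[1]] %in%
                  fixture_alphabet("dna4")))
  # generation must not disturb the session RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_collection(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate fixed-length-zero specs give empty strings", {
  coll <- generate_collection(fixture_spec(d = 2, min_len = 0, max_len = 0,
                                           seed = 1))
  expect_equal(coll$seqs, c("", ""))
})

test_that("uniform sampling gives near-even symbol frequencies", {
  coll <- generate_collection(fixture_spec(d = 1000, alphabet = "dna4",
                                           min_len = 100, max_len = 100,
                                           seed = 3))
  syms <- strsplit(paste(coll$seqs, collapse = ""), "")[[1]]
  n <- length(syms)
  expect_equal(n, 100000L)
  freq <- table(factor(syms, levels = fixture_alphabet("dna4"))) / n
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 5 * se))
})

test_that("the oracle corpus is canonical, reproducible and encodable", {
  corpus <- oracle_corpus()
  expect_length(corpus, 500L)
  expect_identical(corpus[[1]]$coll$seqs,
                   generate_collection(corpus[[1]]$spec)$seqs)
  ds <- vapply(corpus, function(x) x$spec$d, 0L)
  expect_setequal(unique(ds), c(1L, 2L, 4L, 8L))
  sizes <- vapply(corpus, function(x) length(x$spec$alphabet), 0L)
  expect_setequal(unique(sizes), c(2L, 4L, 25L, 90L))
  # a quarter of instances permit empties, spread over every d
  empt <- vapply(corpus, function(x) x$spec$min_len == 0L, FALSE)
  expect_equal(sum(empt), 125L)
  expect_setequal(unique(ds[empt]), c(1L, 2L, 4L, 8L))
  # every instance encodes without error (alphabets exclude reserved bytes)
  for (r in corpus_results()[seq(1, 500, by = 31)]) {
    expect_s3_class(r$ct, "concat_text")
  }
})
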