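#' Built-in fixture alphabets
#'
#' `binary` is a two-letter alphabet, `dna4` the standard nucleotide alphabet,
#' `prot25` the 25-letter IUPAC amino-acid alphabet (20 standard residues plus
#' B, Z, X, U, O), and `ascii90` the 90 printable ASCII characters with codes
#' 33..122.
#'
#' @param name Alphabet name.
#' @return Character vector of single-character symbols.
#' @export
fixture_alphabet <- function(name = c("binary", "dna4", "prot25", "ascii90")) {
  name <- match.arg(name)
  switch(name,
    binary = c("A", "B"),
    dna4 = c("A", "C", "G", "T"),
    prot25 = strsplit("ACDEFGHIKLMNPQRSTVWYBZXUO", "")[[1L]],
    ascii90 = strsplit(intToUtf8(33:122), "")[[1L]]
  )
}

#' Specify a random string collection
#'
#' Each symbol is drawn independently and uniformly from the alphabet (the
#' even-sampling scheme used for random nucleotide and random protein
#' benchmark corpora); lengths are fixed or uniform on an integer range.
#' The same spec always regenerates the same collection.
#'
#' @param d Number of strings.
#' @param alphabet Alphabet name (see [fixture_alphabet()]) or a character
#'   vector of symbols.
#' @param min_len,max_len Inclusive length range; equal values give fixed
#'   lengths.  `min_len = 0` permits empty strings.
#' @param seed Integer RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(d, alphabet = "dna4", min_len = 1L, max_len = 40L,
                         seed = 0L) {
  alph <- if (length(alphabet) == 1L && alphabet %in%
              c("binary", "dna4", "prot25", "ascii90")) {
    fixture_alphabet(alphabet)
  } else {
    as.character(alphabet)
  }
  if (!length(alph)) stop("empty alphabet")
  stopifnot(d >= 1L, min_len >= 0L, max_len >= min_len)
  structure(list(d = as.integer(d), alphabet = alph,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Run code under a private RNG stream, restoring global state afterwards.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the collection a fixture spec describes
#'
#' @param spec A [fixture_spec()].
#' @return A [string_collection()].
#' @examples
#' generate_collection(fixture_spec(d = 4, alphabet = "dna4", seed = 1))
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    lens <- spec$min_len +
      sample.int(spec$max_len - spec$min_len + 1L, spec$d, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(spec$alphabet, L, replace = TRUE), collapse = "")
    }, "")
    string_collection(sprintf("s%d", seq_len(spec$d)), seqs)
  })
}

#' The canonical randomized oracle corpus
#'
#' 500 instances with seeds 0..499, cycling the string count d over
#' 1, 2, 4, 8 and the alphabet over binary, dna4, prot25, ascii90 (all 16
#' combinations), with lengths uniform on 0..40 or 1..40.  A quarter of the
#' instances — spread over every d — permit zero-length strings, exercising
#' adjacent separators throughout the suite.
#'
#' @param n Number of instances (default, and canonical size, 500).
#' @return A list of `n` lists with elements `spec` and `coll`.
#' @export
oracle_corpus <- function(n = 500L) {
  lapply(seq_len(n) - 1L, function(k) {
    d <- c(1L, 2L, 4L, 8L)[k %% 4L + 1L]
    alph <- c("binary", "dna4", "prot25", "ascii90")[(k %/% 4L) %% 4L + 1L]
    allow_empty <- (k %/% 4L) %% 4L == k %% 4L
    spec <- fixture_spec(d = d, alphabet = alph,
                         min_len = if (allow_empty) 0L else 1L,
                         max_len = 40L, seed = k)
    list(spec = spec, coll = generate_collection(spec))
  })
}
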