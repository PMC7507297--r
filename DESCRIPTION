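Package: gsaindex
Title: Suffix Array, LCP, BWT and Document Array Construction for String Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the classical text indexes for a collection of strings in one
    pass: the suffix array of the separator-concatenated text under the order in
    which equal suffixes from different strings are ranked by string number, the
    longest-common-prefix array capped so that matches never cross a separator,
    the multi-string Burrows-Wheeler transform, the document array (directly or
    through a rank bitvector), and the generalized suffix array of
    (string, offset) pairs.  Construction is linear-time induced sorting
    (SA-IS/SACA-K family) implemented in C++, verified against brute-force and
    remapped-alphabet reference implementations.  Collections are read from
    FASTA, FASTQ or raw line-delimited text (optionally gzip-compressed) and all
    arrays are serialized to a documented headerless little-endian binary format
    that can be loaded back and re-validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
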