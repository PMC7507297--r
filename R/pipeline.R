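#' File names used for a serialized index
#' @noRd
.index_files <- function(prefix) {
  list(sa = paste0(prefix, ".sa"), lcp = paste0(prefix, ".lcp"),
       da = paste0(prefix, ".da"), gsa_doc = paste0(prefix, ".gsa.doc"),
       gsa_off = paste0(prefix, ".gsa.off"), bwt = paste0(prefix, ".bwt"),
       txt = paste0(prefix, ".txt"))
}

#' Build index structures for a collection file and write them to disk
#'
#' Reads a collection, encodes it, constructs the requested structures and
#' serializes each to `<prefix>.<ext>`: `.sa`, `.lcp`, `.da` and the GSA pair
#' `.gsa.doc`/`.gsa.off` as headerless little-endian integer arrays of the
#' chosen width, `.bwt` as the `N` rendered BWT bytes, and optionally a
#' human-readable `.txt` dump.  Dependencies are resolved internally: the
#' suffix array is always constructed, and requesting the GSA computes a
#' document array (in light mode when `light = TRUE`) without necessarily
#' writing `.da`.  The run is fully deterministic: the same input produces
#' byte-identical files, and light and direct modes produce identical
#' `.da`/`.gsa` files.
#'
#' @param input Path to the collection (FASTA/FASTQ/text, optionally `.gz`).
#' @param output_prefix Path prefix for output files; defaults to `input`.
#' @param structures Character subset of
#'   `c("sa", "lcp", "da", "gsa", "bwt")`.
#' @param format,gzipped Passed to [read_collection()].
#' @param light Compute the document array through the rank bitvector.
#' @param txt_dump Also write the `.txt` dump.
#' @param width Serialized integer width in bytes (4 or 8); the build refuses
#'   (rather than truncates) values that do not fit.
#' @param verbose Log collection size and per-stage progress.
#' @return Invisibly, a list with `N`, `d`, `sigma` and `files`, the manifest
#'   of written paths.
#' @export
build_indexes <- function(input, output_prefix = input,
                          structures = c("sa", "lcp", "da", "gsa", "bwt"),
                          format = "auto", gzipped = NA, light = FALSE,
                          txt_dump = FALSE, width = 4, verbose = FALSE) {
  structures <- match.arg(structures, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  coll <- read_collection(input, format = format, gzipped = gzipped)
  ct <- encode_collection(coll)
  say("collection: N = %d, d = %d, sigma = %d", ct$N, ct$d, ct$sigma)

  say("suffix array (induced sorting)")
  sa <- gsaca_k(ct)
  lcp <- da <- gsa <- bwt <- NULL
  if ("lcp" %in% structures) { say("LCP array"); lcp <- lcp_from_sa(ct, sa) }
  if (any(c("da", "gsa") %in% structures)) {
    say("document array (%s mode)", if (light) "light" else "direct")
    da <- document_array(ct, sa, mode = if (light) "light" else "direct")
  }
  if ("gsa" %in% structures) { say("generalized suffix array"); gsa <- gsa_from_sa_da(ct, sa, da) }
  if ("bwt" %in% structures || txt_dump) { say("BWT"); bwt <- bwt_from_sa(ct, sa) }

  f <- .index_files(output_prefix)
  files <- list()
  if ("sa" %in% structures) {
    write_int_array(sa, width, f$sa); files$sa <- f$sa
  }
  if ("lcp" %in% structures) {
    write_int_array(lcp, width, f$lcp); files$lcp <- f$lcp
  }
  if ("da" %in% structures) {
    write_int_array(da, width, f$da); files$da <- f$da
  }
  if ("gsa" %in% structures) {
    write_int_array(gsa$docs, width, f$gsa_doc)
    write_int_array(gsa$offs, width, f$gsa_off)
    files$gsa_doc <- f$gsa_doc; files$gsa_off <- f$gsa_off
  }
  if ("bwt" %in% structures) {
    writeBin(charToRaw(render_bwt(bwt)), f$bwt); files$bwt <- f$bwt
  }
  if (txt_dump) {
    write_txt_dump(ct, sa, lcp = lcp, da = da, bwt = bwt, sink = f$txt)
    files$txt <- f$txt
  }
  say("wrote %d file(s) under %s", length(files), output_prefix)
  invisible(list(N = ct$N, d = ct$d, sigma = ct$sigma, files = files))
}

#' Load serialized index structures from disk
#'
#' Reads back whichever of `<prefix>.sa/.lcp/.da/.gsa.doc/.gsa.off/.bwt`
#' exist.  The binary format is headerless, so the integer width must be the
#' one used at write time.
#'
#' @param prefix Path prefix the structures were written under.
#' @param width Integer width in bytes (4 or 8).
#' @return A list with any of `sa`, `lcp`, `da`, `gsa` (a `gsa_pairs`),
#'   `bwt` (a `bwt_codes`), plus `N` when determinable.
#' @export
load_index_files <- function(prefix, width = 4) {
  f <- .index_files(prefix)
  out <- list()
  if (file.exists(f$sa)) out$sa <- read_int_array(f$sa, width)
  if (file.exists(f$lcp)) out$lcp <- read_int_array(f$lcp, width)
  if (file.exists(f$da)) out$da <- read_int_array(f$da, width)
  if (file.exists(f$gsa_doc) && file.exists(f$gsa_off)) {
    out$gsa <- structure(list(docs = read_int_array(f$gsa_doc, width),
                              offs = read_int_array(f$gsa_off, width)),
                         class = "gsa_pairs")
  }
  if (file.exists(f$bwt)) {
    out$bwt <- parse_rendered_bwt(readBin(f$bwt, "raw",
                                          n = file.info(f$bwt)$size))
  }
  lens <- vapply(out[intersect(names(out), c("sa", "lcp", "da", "bwt"))],
                 length, 0L)
  if (length(lens)) out$N <- unname(lens[1L])
  out
}

#' Re-validate serialized index structures against each other
#'
#' Requires at least `.sa` and `.bwt`: the text is reconstructed by
#' scattering `bwt[i]` to position `(sa[i] - 1) mod N`, checked to be a
#' well-formed concatenation, and every other structure present is recomputed
#' from scratch and compared.
#'
#' @param prefix Path prefix.
#' @param width Integer width used at write time.
#' @return A named logical vector of per-structure checks (all `TRUE` on
#'   success); errors if the text cannot be reconstructed.
#' @export
check_index_files <- function(prefix, width = 4) {
  x <- load_index_files(prefix, width)
  if (is.null(x$sa) || is.null(x$bwt)) {
    stop("check requires both <prefix>.sa and <prefix>.bwt")
  }
  N <- length(x$bwt)
  if (length(x$sa) != N) stop("SA and BWT lengths disagree")
  codes <- integer(N)
  codes[((as.integer(x$sa) - 1L) %% N) + 1L] <- as.integer(x$bwt)
  if (codes[N] != 0L || sum(codes == 0L) != 1L) {
    stop("reconstructed text is not end-marker terminated")
  }
  d <- sum(codes == 1L)
  if (d < 1L) stop("reconstructed text has no separators")
  sep_positions <- which(codes == 1L) - 1L
  ct <- structure(list(codes = codes, N = N, d = d, sigma = max(codes) + 1L,
                       starts = c(0L, sep_positions + 1L),
                       sep_positions = sep_positions),
                  class = "concat_text")
  sa2 <- gsaca_k(ct)
  checks <- c(sa = all(x$sa == sa2))
  if (!is.null(x$lcp)) checks["lcp"] <- all(x$lcp == lcp_from_sa(ct, sa2))
  if (!is.null(x$da)) checks["da"] <- all(x$da == document_array(ct, sa2))
  if (!is.null(x$gsa)) {
    g <- gsa_from_sa_da(ct, sa2)
    checks["gsa"] <- all(x$gsa$docs == g$docs) && all(x$gsa$offs == g$offs)
  }
  checks
}
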