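---
title: "Generalized suffix indexing for string collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized suffix indexing for string collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsaindex)
```

## The model

A collection of `d` strings is encoded as a single text
`T = T¹ $ T² $ … Tᵈ $ #` over an integer alphabet in which the end-marker
`#` has code 0, every separator `$` code 1, and content bytes keep their
ASCII values (hence codes ≥ 2; bytes 0 and 1 are rejected at input). The
suffix order the package constructs is lexicographic under an *augmented*
symbol comparison: codes compare numerically, except that two separator
occurrences at positions `p < q` compare as `$ₚ < $_q`. This makes the order
total — two equal suffixes of different strings are ranked by string number —
and it fixes the first `d + 1` rows of the suffix array: the end-marker
suffix, then the separator positions in increasing text order.

Equivalently, the augmented order is the plain suffix order after remapping
the k-th separator occurrence to a distinct code k (and shifting content
codes up by `d`). That equivalence is not just conceptual: it is the
package's primary correctness instrument. `reference_sa()` performs exactly
that remapping and runs an ordinary, pure-R SA-IS; `brute_force_sa()` sorts
the padded suffix matrix of the remapped text directly. Both must agree
with the production construction on every test instance.

## Construction

`gsaca_k()` is an induced-sorting construction (the SA-IS/SACA-K family)
implemented in C++ with the separator convention built in:

- **Type classification.** Position `N−1` is S-type; `T[i]` is S when
  `T[i] < T[i+1]`, L when greater, and on ties inherits from the right —
  except that adjacent separators are S-type, because the earlier occurrence
  is the smaller symbol.
- **Pinned sentinels.** The end-marker and all separator positions are
  placed at rows `0` and `1..d` before each induction and are never
  re-induced. Ordinary induction would impose the L-before-S order inside
  the `$` bucket, but the augmented order within that bucket is positional
  (the final separator, which is L-type, belongs *last*), so induction from
  or into these rows reads them but never rewrites them.
- **LMS naming.** After the first induction sorts the LMS substrings, two
  substrings receive the same name only if they are identical *and* contain
  no separator; any separator-containing LMS substring gets a fresh name,
  issued in text order, which realizes the positional tie-breaking inside
  the recursion. While names repeat, the algorithm recurses on the reduced
  string as plain SA-IS (the reduced alphabet has no special codes — every
  separator name is already unique); when all names are unique the reduced
  order is the inverse permutation. Each level at least halves the problem,
  so the recursion depth is at most `log₂ N`; the depth actually used is
  returned as an attribute.

The constant-workspace trick of reusing suffix-array slots as bucket
counters is deliberately not reproduced: plain per-symbol bucket arrays
(σ ≤ 256 at the top level) are simpler and the output contract — the
augmented order — is what is tested.

`induced_sort_pass()` exposes the induction step itself: given the type map
and the correctly ordered content LMS positions seeded at their bucket
tails, one L-sweep and one S-sweep complete the array. The same C++ routine
backs both phases of the full construction.

## The derived arrays

**Capped LCP.** `LCP[i]` is the longest common prefix of the suffixes at
rows `i` and `i − 1`, computed with a matching predicate that requires equal
codes *and* code ≥ 2. A separator therefore never matches — not even the
same separator compared with itself — so LCP values never reach a string
boundary, and two separator-starting suffixes have LCP 0. Because capping
equals plain matching on the distinct-separator remapping, the Φ/permuted-
LCP sweep (with its `h`-decrement amortization) applies unchanged and runs
in `O(N)`.

**BWT.** `BWT[i] = T[(SA[i] − 1) mod N]`. `invert_bwt()` exists to verify
the transform: it walks the stable LF mapping, which treats all separators
as one symbol. That stability assumption is exactly wrong for separators —
their order in the last column follows the suffixes after them, not their
positional ranks — so the LF permutation can decompose into several cycles.
Content links, however, are exact, so every cycle contains a separator row;
the inversion walks each cycle from a boundary row, splits the emissions at
separators, and drops the single guaranteed-empty segment that precedes the
end-marker. The result is the input multiset of strings; the association of
strings to separators (string order) is intentionally not promised.

**Document array.** `DA[i]` is the string owning suffix `SA[i]`, with the
separator counted as part of the string it terminates and `DA[0] = d + 1`
for the end-marker. The light mode computes `DA[i] = rank₁(SA[i]) + 1` from
a separator bitvector. Rank is *exclusive* of its argument; this is forced,
not chosen: `DA[0] = rank₁(N−1) + 1 = d + 1` requires counting only strictly
earlier positions, and inclusive rank would shift every separator row. The
rank directory is a full prefix-count table — one cumulative count per
position — rather than a block/superblock hierarchy: in R the design goal
is constant-time *vectorized* lookup, and bit-level space savings would buy
nothing here.

**GSA.** Each row becomes `(a, b) = (DA[i], SA[i] − start(a))`. The start
of string `a ≥ 2` can be read off the suffix array itself — row `a − 1`
holds the separator terminating string `a − 1`, so
`start(a) = SA[a − 1] + 1` — or off the encoding's start table. Both routes
are computed and compared on every call, and every pair must round-trip
through `local_to_global()` to the original position. Offsets extend the
per-string definition to all `N` rows: `b = nₐ` is the separator suffix of
string `a`, and `(d + 1, 0)` the end-marker.

## Serialization

Arrays are stored headerless: fixed-width little-endian unsigned integers,
4 bytes by default, 8 when values may reach `2³²` (required once
`N ≥ 2³²`). The BWT file holds the `N` rendered bytes with `#` and `$`
literal; text-mode inputs containing those characters are rejected at read
time so the rendering stays unambiguous (FASTA/FASTQ sequences never
contain them). R represents the values as doubles, so 8-byte values above
`2⁵³` are exact only when representable — a documented limit, not a
practical one at in-memory scales (`N < 2³¹`). `check_index_files()`
validates a saved index with no access to the original input: the text is
reconstructed by scattering `BWT[i]` to position `(SA[i] − 1) mod N`, then
every present structure is recomputed from scratch and compared.

## The synthetic corpus

`generate_collection()` draws every symbol independently and uniformly from
its alphabet — the construction used for random-DNA and random-protein
benchmark corpora — with lengths fixed or uniform on a range, under a
private, explicitly seeded RNG stream (the session RNG is untouched).
`oracle_corpus()` fixes the canonical 500-instance test bed: seeds 0–499,
string counts cycling 1, 2, 4, 8, alphabets cycling binary/DNA-4/protein-25/
printable-ASCII-90 (all 16 combinations), lengths uniform on 0–40 or 1–40.
A quarter of the instances — the phase is chosen so every string count is
covered — allow zero-length strings, which produce adjacent separators and
exercise the S-type-separator rule throughout.

What the corpus emulates is the *combinatorics* of collections: short
strings, small to large alphabets, heavy separator density, empties. What
it does not emulate is real data's LCP statistics — long repeats, read
overlaps, protein domain duplications — or collections at memory scale.
Passing the oracle suite therefore certifies the order and the identities
exactly, at desk scale; the 10 MB random-DNA build (10,000 strings of
1,000 nt, the problem size used by the acceptance script and test suite)
checks that nothing in the implementation is accidentally quadratic and
that recursion stays shallow (depth ≤ log₂ N; observed 4), but it is not a
benchmark.

## Numerical and degenerate-input choices

- All coordinates are 0-based and intervals half-open, matching the field's
  suffix-array conventions; R's 1-based indexing is confined to internals.
- Empty strings are accepted everywhere (a lone separator in the encoding);
  the augmented order needs no special case for them, and the corpus tests
  them continuously. An empty *collection* (`d = 0`) is an error.
- Inputs containing bytes 0 or 1 are rejected with a named error rather
  than remapped: keeping content bytes as their own codes makes encoding
  reversible and bucket arrays small, at the cost of refusing two byte
  values no sequence format uses.
- Width-4 serialization refuses values ≥ 2³² (error names the first
  offending index) instead of truncating.
- The LCP of a suffix with itself is defined by the same capped predicate
  (distance to the first special code); `LCP[0] = 0` by convention.

## Limitations

- In-memory construction is bounded by R's integer indexing (`N < 2³¹`);
  the 8-byte file format is nevertheless supported for interchange.
- The document-array light mode saves the start-table lookup but, unlike a
  succinct implementation, its prefix-count rank table is itself `O(N)`
  words; it exists for the identity and for byte-identical output, not to
  reduce peak memory in R.
- BWT inversion guarantees the string multiset, not the string order.
- Multi-threading and external-memory construction are out of scope.
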