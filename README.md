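# gsaindex

Text indexes — the suffix array, the LCP array, the Burrows–Wheeler
transform, the document array and the generalized suffix array — are the
workhorses of string processing in bioinformatics: suffix–prefix overlap
detection for assembly, read clustering, repeat finding and compact full-text
indexing all start from them. Most construction software targets a single
string; real inputs are usually *collections* (reads, proteins, documents),
and naively concatenating them either inflates the alphabet or wastes time
comparing across string boundaries.

`gsaindex` builds all five structures for a collection of `d` strings
`T¹ … Tᵈ` in linear time. The strings are concatenated as

```
T[0 .. N-1] = T¹ $ T² $ … Tᵈ $ #         N = Σ (nᵢ + 1) + 1
```

with one separator `$` and a final end-marker `#`, ordered `# < $ < a` for
every content symbol `a`, and — the essential convention — **separator
occurrences compare by text position**, so equal suffixes from different
strings are ranked by string number and the suffix order is total. On that
order the package computes:

- **SA** by induced sorting (the SA-IS/SACA-K family) with the separator
  suffixes pinned at their positional ranks, `O(N)` time;
- **LCP** with `LCP[i] = lcp(T_{SA[i]}, T_{SA[i-1]})` capped so that matches
  never include a separator (a `$` matches nothing, not even itself),
  computed in `O(N)` by the Φ/permuted-LCP sweep;
- **BWT** via `BWT[i] = T[(SA[i] − 1) mod N]`, with a verified inversion
  back to the string multiset;
- **DA** (`DA[i]` = string owning suffix `SA[i]`, `DA[0] = d + 1` for the
  end-marker) either directly or, in light mode, through a separator
  bitvector with constant-time rank: `DA[i] = rank₁(SA[i]) + 1`;
- **GSA** as pairs `(a, b)` with `T^a_b` the suffix at `SA[i]`, derived from
  SA and DA by two mutually cross-checking routes.

Every construction is verified against independent oracles: a brute-force
comparison sort and a plain SA-IS run on the text with each separator
remapped to a distinct ascending symbol — the semantic definition of the
rank-tie-breaking order.

## Worked example

```r
library(gsaindex)
coll <- string_collection(c("s1", "s2"), c("AB", "CA"))
ct <- encode_collection(coll)
ct$codes
#> [1] 65 66  1 67 65  1  0        # "AB$CA$#", $ = 1, # = 0

sa <- gsaca_k(ct)
as.integer(sa)
#> [1] 6 2 5 4 0 1 3               # suffixes: #, $₁…, $₂#, A$#, AB$…, B$…, CA$#
lcp_from_sa(ct, sa)
#> [1] 0 0 0 0 1 0 0               # "A$#" and "AB$…" share 1 symbol; $ never matches
document_array(ct, sa)
#> [1] 3 1 2 2 1 1 2               # DA[0] = d + 1 = 3 (end-marker row)
render_bwt(bwt_from_sa(ct, sa))
#> [1] "$BAC#A$"
g <- gsa_from_sa_da(ct, sa)
rbind(doc = g$docs, off = g$offs)
#>     [,1] [,2] [,3] [,4] [,5] [,6] [,7]
#> doc    3    1    2    2    1    1    2
#> off    0    2    2    1    0    1    0   # (a, b): suffix b of string a
invert_bwt(bwt_from_sa(ct, sa), 2)
#> [1] "AB" "CA"
```

Row 4 of the GSA reads `(1, 0)`: the fifth-smallest suffix is all of string
1 (`AB$…`). Offsets `b = nₐ` address the separator terminating string `a`,
and `(d + 1, 0)` the end-marker.

## Files on disk

`build_indexes()` (or the `exec/gsaindex` command line: `gsaindex build
input.fa --sa --lcp --gsa --bwt --output prefix`) writes `<prefix>.sa`,
`.lcp`, `.da`, `.gsa.doc`, `.gsa.off` as headerless little-endian integer
arrays (4 or 8 bytes per value), `<prefix>.bwt` as the `N` rendered BWT
bytes (`#`/`$` literal), and optionally a tab-separated `.txt` dump.
`load_index_files()` reads them back and `check_index_files()` reconstructs
the text from SA + BWT and re-derives every other structure to validate a
saved index.

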