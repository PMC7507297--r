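#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Induced-sorting suffix array construction for a separator-delimited
// concatenation T[0..n-1] with end-marker code 0 at position n-1, d separator
// occurrences with code 1, and content codes >= 2.  The target order is
// lexicographic with every separator occurrence treated as a distinct symbol,
// increasing with text position (so equal suffixes of different strings are
// ranked by string number).  Recursion levels work on reduced strings with no
// special codes and run as plain SA-IS.

namespace {

// L/S classification under the augmented comparison: two separator
// occurrences at p < q compare as T[p] < T[q], so equal code-1 neighbours are
// S-type; equal content codes inherit the type to their right.
void compute_types(const std::vector<int>& T, std::vector<char>& tS, bool sep) {
  const int n = (int)T.size();
  tS.assign(n, 0);
  tS[n - 1] = 1;
  for (int i = n - 2; i >= 0; --i) {
    if (T[i] < T[i + 1]) tS[i] = 1;
    else if (T[i] > T[i + 1]) tS[i] = 0;
    else tS[i] = (sep && T[i] == 1) ? 1 : tS[i + 1];
  }
}

// One full induction: left-to-right sweep placing L-type predecessors at
// bucket heads, then right-to-left placing S-type predecessors at bucket
// tails.  In sep mode positions holding codes 0/1 are pre-placed by rank and
// must never be re-induced (their within-bucket order is positional, not the
// L-before-S order ordinary induction would impose).
void induce_pass(const std::vector<int>& T, const std::vector<char>& tS,
                 const std::vector<int>& cnt, int K, std::vector<int>& SA,
                 bool sep) {
  const int n = (int)T.size();
  std::vector<int> bkt(K);
  int s = 0;
  for (int c = 0; c < K; ++c) { bkt[c] = s; s += cnt[c]; }
  for (int i = 0; i < n; ++i) {
    int j = SA[i];
    if (j > 0) {
      int k = j - 1;
      if (!tS[k] && !(sep && T[k] < 2)) SA[bkt[T[k]]++] = k;
    }
  }
  s = 0;
  for (int c = 0; c < K; ++c) { s += cnt[c]; bkt[c] = s; }
  for (int i = n - 1; i >= 0; --i) {
    int j = SA[i];
    if (j > 0) {
      int k = j - 1;
      if (tS[k] && !(sep && T[k] < 2)) SA[--bkt[T[k]]] = k;
    }
  }
}

// Returns recursion depth (>= 1).
int sais(const std::vector<int>& T, std::vector<int>& SA, int K, bool sep) {
  const int n = (int)T.size();
  SA.assign(n, -1);
  if (n == 1) { SA[0] = 0; return 1; }

  std::vector<char> tS;
  compute_types(T, tS, sep);

  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[T[i]]++;

  std::vector<int> lms;                       // LMS positions, text order
  std::vector<char> isLMS(n, 0);
  for (int i = 1; i < n; ++i)
    if (tS[i] && !tS[i - 1]) { lms.push_back(i); isLMS[i] = 1; }
  const int nlms = (int)lms.size();

  std::vector<int> bkt(K);
  auto preplace = [&]() {
    std::fill(SA.begin(), SA.end(), -1);
    if (sep) {
      SA[0] = n - 1;                          // end-marker suffix is smallest
      int r = 1;
      for (int i = 0; i < n; ++i)             // separators by ascending position
        if (T[i] == 1) SA[r++] = i;
    }
  };

  // Phase A: sort the LMS substrings by one induction from text-order seeds.
  preplace();
  int s = 0;
  for (int c = 0; c < K; ++c) { s += cnt[c]; bkt[c] = s; }
  for (int z = nlms - 1; z >= 0; --z) {
    int p = lms[z];
    if (sep && T[p] < 2) continue;            // sentinel/separator pre-placed
    SA[--bkt[T[p]]] = p;
  }
  induce_pass(T, tS, cnt, K, SA, sep);

  // Name LMS substrings in sorted order.  Two substrings share a name only
  // when byte-identical AND free of special codes; any substring containing a
  // separator gets a fresh name, so separators keep their positional ranks.
  std::vector<int> sorted;
  sorted.reserve(nlms);
  for (int i = 0; i < n; ++i) {
    int j = SA[i];
    if (j >= 0 && isLMS[j]) sorted.push_back(j);
  }
  std::vector<int> name(n, -1);
  int cur = -1, prev = -1;
  for (int z = 0; z < nlms; ++z) {
    int p = sorted[z];
    bool diff = false;
    if (prev < 0) diff = true;
    else {
      for (int k = 0;; ++k) {
        if (p + k >= n || prev + k >= n) { diff = true; break; }
        bool pe = (k > 0 && isLMS[p + k]);
        bool qe = (k > 0 && isLMS[prev + k]);
        if (pe && qe) break;                  // both substrings ended, equal
        if (pe != qe || T[p + k] != T[prev + k]) { diff = true; break; }
        if (sep && T[p + k] < 2) { diff = true; break; }
      }
    }
    if (diff) { ++cur; prev = p; }
    name[p] = cur;
  }
  const int nnames = cur + 1;

  // Order of LMS suffixes, via recursion when names repeat.
  int depth = 1;
  std::vector<int> salms(nlms);
  if (nnames < nlms) {
    std::vector<int> s1(nlms);
    for (int z = 0; z < nlms; ++z) s1[z] = name[lms[z]];
    std::vector<int> SA1;
    depth = 1 + sais(s1, SA1, nnames, false);
    for (int z = 0; z < nlms; ++z) salms[z] = lms[SA1[z]];
  } else {
    for (int z = 0; z < nlms; ++z) salms[name[lms[z]]] = lms[z];
  }

  // Phase B: seed the fully ordered LMS suffixes and induce the final array.
  preplace();
  s = 0;
  for (int c = 0; c < K; ++c) { s += cnt[c]; bkt[c] = s; }
  for (int z = nlms - 1; z >= 0; --z) {
    int p = salms[z];
    if (sep && T[p] < 2) continue;
    SA[--bkt[T[p]]] = p;
  }
  induce_pass(T, tS, cnt, K, SA, sep);
  return depth;
}

}  // namespace

// [[Rcpp::export]]
List cpp_gsaca_k(IntegerVector codes) {
  const int n = codes.size();
  std::vector<int> T(codes.begin(), codes.end());
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, T[i]);
  ++K;
  std::vector<int> SA;
  int depth = sais(T, SA, K, true);
  return List::create(_["sa"] = IntegerVector(SA.begin(), SA.end()),
                      _["depth"] = depth);
}

// Single induction from a seeded partial array: `seeded` holds 0-based text
// positions or NA for empty slots.  End-marker and separator positions are
// (re-)placed by rank before sweeping; everything else is taken as given.
// [[Rcpp::export]]
IntegerVector cpp_induce(IntegerVector codes, LogicalVector is_s,
                         IntegerVector seeded) {
  const int n = codes.size();
  std::vector<int> T(codes.begin(), codes.end());
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, T[i]);
  ++K;
  std::vector<char> tS(n);
  for (int i = 0; i < n; ++i) tS[i] = is_s[i] ? 1 : 0;
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[T[i]]++;
  std::vector<int> SA(n);
  for (int i = 0; i < n; ++i)
    SA[i] = (seeded[i] == NA_INTEGER) ? -1 : seeded[i];
  SA[0] = n - 1;
  int r = 1;
  for (int i = 0; i < n; ++i)
    if (T[i] == 1) SA[r++] = i;
  induce_pass(T, tS, cnt, K, SA, true);
  return IntegerVector(SA.begin(), SA.end());
}

// Capped LCP via the Phi/permuted-LCP sweep: h never drops by more than one
// between consecutive text positions because the capped comparison equals the
// plain comparison on the distinct-separator remapping of the text.
// [[Rcpp::export]]
IntegerVector cpp_lcp_phi(IntegerVector codes, IntegerVector sa) {
  const int n = codes.size();
  std::vector<int> phi(n, -1);
  for (int i = 1; i < n; ++i) phi[sa[i]] = sa[i - 1];
  std::vector<int> plcp(n, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    int j = phi[i];
    if (j < 0) { h = 0; plcp[i] = 0; continue; }
    while (i + h < n && j + h < n && codes[i + h] == codes[j + h] &&
           codes[i + h] >= 2)
      ++h;
    plcp[i] = h;
    if (h > 0) --h;
  }
  IntegerVector lcp(n);
  lcp[0] = 0;
  for (int i = 1; i < n; ++i) lcp[i] = plcp[sa[i]];
  return lcp;
}
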