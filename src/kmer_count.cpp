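#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3; anything else (incl. N) = 4.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// Sparse canonical k-mer counts over a set of sequences.
//
// Rolling 2-bit encoding of the forward and reverse-complement codes of the
// current window; the counter key is min(fwd, rc). A window containing any
// non-ACGT character is skipped and the roll restarts after it (reset-on-N).
// Requires 1 <= k <= 26 so every code is exactly representable in the double
// returned to R (2k <= 52 mantissa bits).
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 26)
    stop("k must be in [1, 26]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  std::unordered_map<uint64_t, double> counts;
  double total = 0.0;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int filled = 0; // valid bases currently in the window
    for (const char *p = seq; *p; ++p) {
      int b = base_code(*p);
      if (b == 4) { filled = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << rc_shift);
      if (filled < k) ++filled;
      if (filled == k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        counts[canon] += 1.0;
        total += 1.0;
      }
    }
  }

  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  NumericVector codes(keys.size()), vals(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    codes[i] = (double)keys[i];
    vals[i] = counts[keys[i]];
  }
  return List::create(_["codes"] = codes, _["counts"] = vals,
                      _["total"] = total);
}

// Dot product of two sparse profiles with sorted code keys (merge join).
// [[Rcpp::export]]
double sparse_dot_cpp(NumericVector codes1, NumericVector x1,
                      NumericVector codes2, NumericVector x2) {
  R_xlen_t i = 0, j = 0;
  double dot = 0.0;
  while (i < codes1.size() && j < codes2.size()) {
    if (codes1[i] < codes2[j]) ++i;
    else if (codes1[i] > codes2[j]) ++j;
    else { dot += x1[i] * x2[j]; ++i; ++j; }
  }
  return dot;
}
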