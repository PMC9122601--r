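#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Mismatch-tolerant inverted-repeat scan by centre expansion.
//
// For every inner boundary e (= arm1_end, 0-based) and spacer g in
// [0, max_gap], arms of length k are [e-k, e) and [e+g, e+g+k).  Growing k
// adds one outermost base pair, so the mismatch count between arm1 and
// revcomp(arm2) is non-decreasing in k; the unique maximal repeat per
// (e, g) is the largest k within the mismatch budget and the sequence
// bounds.  Shorter repeats with the same inner boundary and spacer are by
// construction extendable, hence non-maximal, and are never emitted
// (equivalently: repeats wholly contained in a longer reported repeat with
// equal spacer are suppressed).  N never pairs with anything, including N.

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;   // N or invalid: pairs with nothing
  }
}

struct IRHit { int a1s, a1e, a2s, a2e, k, g, mm; };

// [[Rcpp::export(name = ".find_ir")]]
DataFrame find_ir(std::string seq, int min_arm, int max_gap, int max_mismatch,
                  bool total_semantics) {
  const int L = seq.size();
  std::vector<IRHit> hits;
  for (int e = 1; e < L; ++e) {
    for (int g = 0; g <= max_gap; ++g) {
      int k = 0, mm = 0, k_best = 0, mm_best = 0;
      while (e - (k + 1) >= 0 && e + g + k + 1 <= L) {
        // outermost pair for arm length k+1
        char a = seq[e - (k + 1)];
        char b = seq[e + g + k];
        int add = (comp(a) != 0 && comp(a) == b) ? 0 : 1;
        if (mm + add > max_mismatch) break;
        mm += add; ++k;
        k_best = k; mm_best = mm;
      }
      bool pass = total_semantics ? (2 * k_best + g >= min_arm)
                                  : (k_best >= min_arm);
      if (k_best > 0 && pass) {
        hits.push_back({e - k_best, e, e + g, e + g + k_best,
                        k_best, g, mm_best});
      }
    }
  }
  std::sort(hits.begin(), hits.end(), [](const IRHit& x, const IRHit& y) {
    if (x.a1s != y.a1s) return x.a1s < y.a1s;
    if (x.k != y.k) return x.k > y.k;        // longer arms first
    return x.g < y.g;
  });
  const int nh = hits.size();
  IntegerVector a1s(nh), a1e(nh), a2s(nh), a2e(nh), k(nh), g(nh), mm(nh);
  for (int i = 0; i < nh; ++i) {
    a1s[i] = hits[i].a1s; a1e[i] = hits[i].a1e;
    a2s[i] = hits[i].a2s; a2e[i] = hits[i].a2e;
    k[i] = hits[i].k; g[i] = hits[i].g; mm[i] = hits[i].mm;
  }
  return DataFrame::create(
    _["arm1_start"] = a1s, _["arm1_end"] = a1e,
    _["arm2_start"] = a2s, _["arm2_end"] = a2e,
    _["arm_len"] = k, _["spacer_len"] = g, _["mismatches"] = mm,
    _["stringsAsFactors"] = false);
}
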