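#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman / Gotoh local alignment with affine gaps.
// Gap of length k costs gap_open + k * gap_extend (BLAST convention).
// Tie-breaking is fixed for determinism: among equal-scoring end cells the
// smallest (subject_end, query_end) wins; traceback prefers diagonal over
// gap-in-subject over gap-in-query.

static void build_index(const IntegerMatrix& mat, int idx[256]) {
  CharacterVector rn = rownames(mat);
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) idx[(unsigned char)s[0]] = i;
  }
}

static inline int sub_score(const IntegerMatrix& mat, const int idx[256],
                            char a, char b) {
  int ia = idx[(unsigned char)a], ib = idx[(unsigned char)b];
  if (ia < 0) ia = idx[(unsigned char)'X'];
  if (ib < 0) ib = idx[(unsigned char)'X'];
  if (ia < 0 || ib < 0)
    stop("local_align: residue not in substitution matrix and no 'X' row");
  return mat(ia, ib);
}

// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(std::string query, std::string subject,
                 IntegerMatrix matrix, int gap_open, int gap_extend) {
  const int m = query.size(), n = subject.size();
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["n_match"] = 0,
                        _["aln_len"] = 0, _["identity_frac"] = NA_REAL);
  }
  int idx[256];
  build_index(matrix, idx);
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend;   // cost of a length-1 gap
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);  // gap in query (consumes subject)
  std::vector<int> F((m + 1) * (n + 1), NEG);  // gap in subject (consumes query)
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] - go, E[at(i, j - 1)] - gap_extend);
      int f = std::max(H[at(i - 1, j)] - go, F[at(i - 1, j)] - gap_extend);
      int d = H[at(i - 1, j - 1)] + sub_score(matrix, idx, query[i - 1], subject[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[at(i, j)] = e; F[at(i, j)] = f; H[at(i, j)] = h;
      if (h > best || (h == best && h > 0 &&
                       (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0, _["n_match"] = 0,
                        _["aln_len"] = 0, _["identity_frac"] = NA_REAL);
  }
  // traceback from (bi, bj); state 0 = H, 1 = E (gap in query), 2 = F
  int i = bi, j = bj, state = 0, n_match = 0, aln_len = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int d = H[at(i - 1, j - 1)] + sub_score(matrix, idx, query[i - 1], subject[j - 1]);
      if (h == d) {
        if (query[i - 1] == subject[j - 1]) ++n_match;
        ++aln_len; --i; --j;
      } else if (h == F[at(i, j)]) {
        state = 2;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else {
        stop("internal traceback error");  // unreachable
      }
    } else if (state == 1) {
      ++aln_len;
      if (E[at(i, j)] == H[at(i, j - 1)] - go) { --j; state = 0; }
      else { --j; }
    } else {
      ++aln_len;
      if (F[at(i, j)] == H[at(i - 1, j)] - go) { --i; state = 0; }
      else { --i; }
    }
  }
  // spans reported 1-based inclusive (tabular-homology convention)
  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["s_start"] = j + 1, _["s_end"] = bj,
    _["n_match"] = n_match, _["aln_len"] = aln_len,
    _["identity_frac"] = aln_len > 0 ? (double)n_match / aln_len : NA_REAL);
}
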