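#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Gap costs follow the BLAST convention:
// a gap of length L costs open + L * extend (both passed as positive
// integers), i.e. the first gapped residue costs open + extend.
// Sequences arrive as 0-based integer codes into the substitution matrix.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
int sw_score_cpp(const IntegerVector& a, const IntegerVector& b,
                 const IntegerMatrix& mat, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int E = NEG;
    int prev_diag = 0; // H[i-1][0]
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int up = H[j]; // still H[i-1][j]
      F[j] = std::max(up - gap_open - gap_extend, F[j] - gap_extend);
      E = std::max(H[j - 1] - gap_open - gap_extend, E - gap_extend);
      int h = prev_diag + mat(ai, b[j - 1]);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      H[j] = h;
      prev_diag = up;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full alignment with traceback. Tie-breaks are deterministic: the end
// cell with maximal score and smallest subject index (then query index)
// is chosen, and at each traceback step diagonal is preferred over the
// vertical (query-consuming) move, which is preferred over horizontal.
// Returns 0-based half-open spans and aligned code vectors (-1 = gap).
// [[Rcpp::export]]
List sw_traceback_cpp(const IntegerVector& a, const IntegerVector& b,
                      const IntegerMatrix& mat, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  IntegerMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { H(0, j) = 0; E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { H(i, 0) = 0; E(i, 0) = NEG; F(i, 0) = NEG; }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      int h = H(i - 1, j - 1) + mat(a[i - 1], b[j - 1]);
      if (E(i, j) > h) h = E(i, j);
      if (F(i, j) > h) h = F(i, j);
      if (h < 0) h = 0;
      H(i, j) = h;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
  }
  std::vector<int> aa, ba; // aligned codes, reversed
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (horizontal), 2 = F (vertical)
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H(i, j) == 0) break;
      const int diag = H(i - 1, j - 1) + mat(a[i - 1], b[j - 1]);
      if (H(i, j) == diag) {
        aa.push_back(a[i - 1]); ba.push_back(b[j - 1]);
        --i; --j;
      } else if (H(i, j) == F(i, j)) {
        state = 2;
      } else { // E
        state = 1;
      }
    } else if (state == 2) { // vertical: consume a[i-1], gap in b
      aa.push_back(a[i - 1]); ba.push_back(-1);
      const bool open_here = (F(i, j) == H(i - 1, j) - gap_open - gap_extend);
      --i;
      if (open_here) state = 0;
    } else { // horizontal: consume b[j-1], gap in a
      aa.push_back(-1); ba.push_back(b[j - 1]);
      const bool open_here = (E(i, j) == H(i, j - 1) - gap_open - gap_extend);
      --j;
      if (open_here) state = 0;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ba.begin(), ba.end());
  return List::create(
    _["score"] = best,
    _["a_start"] = i, _["a_end"] = bi,
    _["b_start"] = j, _["b_end"] = bj,
    _["aligned_a"] = IntegerVector(aa.begin(), aa.end()),
    _["aligned_b"] = IntegerVector(ba.begin(), ba.end()));
}
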