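#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment.
//
// Gap convention: a gap run of length L costs gap_open + (L-1) * gap_extend,
// with gap_open <= gap_extend <= 0. Traceback ties are broken by fixed
// operator order diagonal > up (gap in b) > left (gap in a) so results are
// deterministic. For local mode the end cell is the first maximum in
// row-major order.
//
// a, b: 1-based integer codes into the substitution matrix S.
// Returns score plus aligned code vectors (0 = gap).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  // state 0 = M (diag), 1 = X (up, consumes a), 2 = Y (left, consumes b)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF)),
      X = M, Y = M;
  // traceback: predecessor state + whether M started fresh (local)
  std::vector<std::vector<signed char>> pM(n + 1, std::vector<signed char>(m + 1, -1)),
      pX = pM, pY = pM;

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (local) { M[i][0] = NEG_INF; X[i][0] = NEG_INF; }
    else { X[i][0] = gap_open + (i - 1) * gap_extend; pX[i][0] = (i == 1) ? 0 : 1; }
  }
  for (int j = 1; j <= m; ++j) {
    if (!local) { Y[0][j] = gap_open + (j - 1) * gap_extend; pY[0][j] = (j == 1) ? 0 : 2; }
  }
  if (local) for (int i = 0; i <= n; ++i) M[i][0] = (i == 0) ? 0.0 : NEG_INF;

  double best = 0.0; int bi = 0, bj = 0;  // local end cell
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double sub = S(a[i - 1] - 1, b[j - 1] - 1);
      // M: prefer diag(M) > X > Y > fresh start
      double v = M[i - 1][j - 1]; signed char p = 0;
      if (X[i - 1][j - 1] > v) { v = X[i - 1][j - 1]; p = 1; }
      if (Y[i - 1][j - 1] > v) { v = Y[i - 1][j - 1]; p = 2; }
      if (local && 0.0 > v) { v = 0.0; p = 3; }  // fresh start
      M[i][j] = (v == NEG_INF) ? NEG_INF : v + sub;
      pM[i][j] = p;
      // X (up): gap in b
      v = M[i - 1][j] + gap_open; p = 0;
      if (X[i - 1][j] + gap_extend > v) { v = X[i - 1][j] + gap_extend; p = 1; }
      if (Y[i - 1][j] + gap_open > v) { v = Y[i - 1][j] + gap_open; p = 2; }
      X[i][j] = v; pX[i][j] = p;
      // Y (left): gap in a
      v = M[i][j - 1] + gap_open; p = 0;
      if (X[i][j - 1] + gap_open > v) { v = X[i][j - 1] + gap_open; p = 1; }
      if (Y[i][j - 1] + gap_extend > v) { v = Y[i][j - 1] + gap_extend; p = 2; }
      Y[i][j] = v; pY[i][j] = p;
      if (local && M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }

  double score;
  int state;  // 0 M, 1 X, 2 Y
  int i, j;
  if (local) {
    score = best; i = bi; j = bj; state = 0;
    if (best <= 0.0) {  // empty alignment
      return List::create(_["score"] = 0.0,
                          _["a_aln"] = IntegerVector(0),
                          _["b_aln"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
  } else {
    i = n; j = m;
    score = M[n][m]; state = 0;
    if (X[n][m] > score) { score = X[n][m]; state = 1; }
    if (Y[n][m] > score) { score = Y[n][m]; state = 2; }
  }

  std::vector<int> ar, br;  // reversed aligned codes, 0 = gap
  int a_end = (local ? i : n), b_end = (local ? j : m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char p = pM[i][j];
      ar.push_back(a[i - 1]); br.push_back(b[j - 1]);
      --i; --j;
      if (p == 3) break;  // local fresh start: this cell opened the alignment
      state = p;
    } else if (state == 1) {
      signed char p = pX[i][j];
      ar.push_back(a[i - 1]); br.push_back(0);
      --i; state = p;
    } else {
      signed char p = pY[i][j];
      ar.push_back(0); br.push_back(b[j - 1]);
      --j; state = p;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());
  int a_start = a_end, b_start = b_end;
  for (size_t k = 0; k < ar.size(); ++k) if (ar[k] > 0) --a_start;
  for (size_t k = 0; k < br.size(); ++k) if (br[k] > 0) --b_start;
  return List::create(_["score"] = score,
                      _["a_aln"] = IntegerVector(ar.begin(), ar.end()),
                      _["b_aln"] = IntegerVector(br.begin(), br.end()),
                      _["a_start"] = a_start + 1, _["a_end"] = a_end,
                      _["b_start"] = b_start + 1, _["b_end"] = b_end);
}
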