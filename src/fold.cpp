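#include <Rcpp.h>
using namespace Rcpp;

// Score cloverleaf candidate layouts over a base-coded tRNA sequence.
// bases: 1=A, 2=C, 3=G, 4=T (0 = other; always scores as mismatch).
// grid columns: s1, d, ld, s2, lv, t, lt. Returns score and acceptor-WC
// count per candidate. Pair scores: WC +2, G-U wobble +1, mismatch -1.
// [[Rcpp::export]]
NumericMatrix score_layouts_cpp(IntegerVector bases, IntegerMatrix grid) {
  const int n = bases.size(), m = grid.nrow();
  // pair score lookup, 1-based codes
  double P[5][5];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) P[i][j] = -1.0;
  P[1][4] = P[4][1] = P[3][2] = P[2][3] = 2.0;  // A:T, T:A, G:C, C:G
  P[3][4] = P[4][3] = 1.0;                      // G:T, T:G
  NumericMatrix out(m, 2);
  for (int r = 0; r < m; ++r) {
    const int s1 = grid(r, 0), d = grid(r, 1), ld = grid(r, 2),
              s2 = grid(r, 3), lv = grid(r, 4), t = grid(r, 5),
              lt = grid(r, 6);
    double score = 0.0;
    int acc_wc = 0;
    // acceptor stem: i pairs with n - 1 - i (0-based), 7 pairs
    for (int i = 0; i < 7; ++i) {
      const double s = P[bases[i]][bases[n - 2 - i]];
      score += s;
      if (s == 2.0) ++acc_wc;
    }
    int pos = 7 + s1;  // 0-based index of first DHU-stem base
    for (int i = 0; i < d; ++i)
      score += P[bases[pos + i]][bases[pos + 2 * d + ld - 1 - i]];
    pos += 2 * d + ld + s2;
    for (int i = 0; i < 5; ++i)
      score += P[bases[pos + i]][bases[pos + 16 - i]];
    pos += 17 + lv;
    for (int i = 0; i < t; ++i)
      score += P[bases[pos + i]][bases[pos + 2 * t + lt - 1 - i]];
    out(r, 0) = score;
    out(r, 1) = acc_wc;
  }
  return out;
}
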