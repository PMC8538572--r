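#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Gotoh affine-gap global alignment with a fixed deterministic tie-break:
// at equal score prefer the diagonal (match/mismatch) state, then a gap in
// the first sequence, then a gap in the second. Gap of length L costs
// gap_open + (L - 1) * gap_extend (both negative penalties).
//
// States: 0 = M (diagonal), 1 = Y (gap in first seq, consumes b),
// 2 = X (gap in second seq, consumes a).
// [[Rcpp::export]]
List align_global_cpp(std::string a, std::string b, double match,
                      double mismatch, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: which predecessor state fed each cell's state
  std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
      tbY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_extend;
    tbX[i * W] = 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    tbY[j] = 1;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: best of three predecessors, preference M > Y > X
      double best = M[d];
      unsigned char st = 0;
      if (Y[d] > best) { best = Y[d]; st = 1; }
      if (X[d] > best) { best = X[d]; st = 2; }
      M[c] = best + sub;
      tbM[c] = st;
      // Y: gap in first sequence (consume b[j-1])
      best = M[l] + gap_open;
      st = 0;
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; st = 1; }
      if (X[l] + gap_open > best) { best = X[l] + gap_open; st = 2; }
      Y[c] = best;
      tbY[c] = st;
      // X: gap in second sequence (consume a[i-1])
      best = M[u] + gap_open;
      st = 0;
      if (Y[u] + gap_open > best) { best = Y[u] + gap_open; st = 1; }
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; st = 2; }
      X[c] = best;
      tbX[c] = st;
    }
  }

  const size_t end = (size_t)n * W + m;
  double score = M[end];
  unsigned char state = 0;
  if (Y[end] > score) { score = Y[end]; state = 1; }
  if (X[end] > score) { score = X[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = tbM[c];
      --i; --j;
    } else if (state == 1) {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = tbY[c];
      --j;
    } else {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = tbX[c];
      --i;
    }
  }
  std::string fa(ra.rbegin(), ra.rend()), fb(rb.rbegin(), rb.rend());
  return List::create(_["a"] = fa, _["b"] = fb, _["score"] = score);
}
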