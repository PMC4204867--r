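#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dynamic time warping between two time-frequency matrices (channels x frames)
// with the symmetric Sakoe-Chiba step set (1,0),(0,1),(1,1), diagonal weight 2,
// and normalization by (n + m). The first cell carries weight 2 so that the
// degenerate one-frame-per-side case returns the frame metric itself.
// [[Rcpp::export(name = ".dtw_core")]]
double dtw_core(NumericMatrix a, NumericMatrix b) {
  const int nc = a.nrow();
  if (b.nrow() != nc) stop("channel count mismatch");
  const int n = a.ncol(), m = b.ncol();

  // local Euclidean frame distances
  NumericMatrix d(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < nc; ++c) {
        double diff = a(c, i) - b(c, j);
        s += diff * diff;
      }
      d(i, j) = std::sqrt(s);
    }
  }

  std::vector<double> prev(m), cur(m);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dij = d(i, j);
      double best;
      if (i == 0 && j == 0) {
        best = 2.0 * dij;
      } else {
        best = inf;
        if (i > 0) best = std::min(best, prev[j] + dij);
        if (j > 0) best = std::min(best, cur[j - 1] + dij);
        if (i > 0 && j > 0) best = std::min(best, prev[j - 1] + 2.0 * dij);
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1] / (double)(n + m);
}
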