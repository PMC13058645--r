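#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Windowed cross-correlation core.
//
// For window start s (0-based) of width w and signed lag L, correlates the
// participant p(t) with the assessor a(t - L) over the part of the window
// where both indices fall inside it: t in [s + max(L,0), s + w - 1 + min(L,0)].
// Positive lag means the assessor's movement leads the participant's.
// Cells where either segment has zero variance are NaN (invalid).
//
// [[Rcpp::export(name = ".wcc_core")]]
NumericMatrix wcc_core(NumericVector p, NumericVector a,
                       int window, int stride, int max_lag) {
  const int n = p.size();
  if (a.size() != n) stop("series lengths differ");
  if (window + max_lag > n) stop("series too short for window + max_lag");
  if (window - max_lag < 3) stop("window minus max_lag leaves fewer than 3 points");
  const int n_win = (n - window) / stride + 1;
  const int n_lag = 2 * max_lag + 1;
  NumericMatrix z(n_win, n_lag);

  for (int wi = 0; wi < n_win; ++wi) {
    const int s = wi * stride;
    for (int li = 0; li < n_lag; ++li) {
      const int L = li - max_lag;
      const int t0 = s + (L > 0 ? L : 0);
      const int t1 = s + window - 1 + (L < 0 ? L : 0);
      const int m = t1 - t0 + 1;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      for (int t = t0; t <= t1; ++t) {
        const double xv = p[t];
        const double yv = a[t - L];
        sx += xv; sy += yv;
        sxx += xv * xv; syy += yv * yv; sxy += xv * yv;
      }
      const double vx = sxx - sx * sx / m;
      const double vy = syy - sy * sy / m;
      if (vx <= 0.0 || vy <= 0.0) {
        z(wi, li) = NA_REAL;
      } else {
        double r = (sxy - sx * sy / m) / std::sqrt(vx * vy);
        if (r > 1.0) r = 1.0;
        if (r < -1.0) r = -1.0;
        z(wi, li) = r;
      }
    }
  }
  return z;
}
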