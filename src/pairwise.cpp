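#include <Rcpp.h>
using namespace Rcpp;

// Soft-core pairwise interaction, averaged over neighbours within R_i.
// Repulsion: -R_i * (xk - xj) / |xk - xj|^2  (magnitude R_i/d).
// Attraction (optional): (xk - xj) / |xk - xj| (unit magnitude).
// Coincident agents (d < 1e-9 m) get the capped repulsion R_i/1e-9 along a
// random direction drawn from R's RNG stream.
// [[Rcpp::export]]
NumericMatrix pairwise_forces_cpp(NumericVector x, NumericVector y,
                                  double Ri, bool repel, bool attract) {
  const int n = x.size();
  NumericMatrix out(n, 2);
  if (n < 2 || (!repel && !attract)) return out;
  const double Ri2 = Ri * Ri, dmin = 1e-9;
  std::vector<double> fx(n, 0.0), fy(n, 0.0);
  std::vector<int> cnt(n, 0);
  for (int j = 0; j < n; ++j) {
    for (int k = j + 1; k < n; ++k) {
      double dx = x[k] - x[j], dy = y[k] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > Ri2) continue;
      double cx = 0.0, cy = 0.0;  // contribution on j from k
      double d = std::sqrt(d2);
      if (d < dmin) {
        double ang = 2.0 * M_PI * unif_rand();
        double mag = repel ? (Ri / dmin) : 0.0;
        cx = -mag * std::cos(ang);
        cy = -mag * std::sin(ang);
      } else {
        if (repel)   { cx += -Ri * dx / d2; cy += -Ri * dy / d2; }
        if (attract) { cx += dx / d;        cy += dy / d; }
      }
      fx[j] += cx;       fy[j] += cy;       cnt[j]++;
      fx[k] -= cx;       fy[k] -= cy;       cnt[k]++;
    }
  }
  for (int j = 0; j < n; ++j) {
    if (cnt[j] > 0) {
      out(j, 0) = fx[j] / cnt[j];
      out(j, 1) = fy[j] / cnt[j];
    }
  }
  return out;
}
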