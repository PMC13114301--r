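#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear interpolation in log(r) on a tabulated radial function,
// value held constant beyond either end (the caller's geometry factor
// supplies the inverse-square tail).  Matches the R-side interpolation.
static inline double interp_logr(const double *lr, const double *v,
                                 const int n, const double logr) {
  if (logr <= lr[0]) return v[0];
  if (logr >= lr[n - 1]) return v[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (lr[mid] <= logr) lo = mid; else hi = mid;
  }
  double w = (logr - lr[lo]) / (lr[lo + 1] - lr[lo]);
  return v[lo] * (1 - w) + v[lo + 1] * w;
}

// Superpose the radial part of the TG-43 point-source dose rate over all
// voxel centers: sum over seeds of (r0/r)^2 * g(r) * phi_an(r), with r
// clamped at r_min.  Tables are passed as log(radius) nodes plus values;
// units cm, r0 = 1 cm folded into the caller's constants.
// [[Rcpp::export]]
NumericVector tg43_superpose(NumericMatrix points, NumericMatrix seeds,
                             NumericVector g_logr, NumericVector g_val,
                             NumericVector p_logr, NumericVector p_val,
                             double r_min) {
  const int n = points.nrow(), m = seeds.nrow();
  const int ng = g_logr.size(), np = p_logr.size();
  NumericVector out(n);
  const double *px = &points(0, 0), *py = &points(0, 1), *pz = &points(0, 2);
  for (int s = 0; s < m; ++s) {
    const double sx = seeds(s, 0), sy = seeds(s, 1), sz = seeds(s, 2);
    for (int i = 0; i < n; ++i) {
      double dx = px[i] - sx, dy = py[i] - sy, dz = pz[i] - sz;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < r_min) r = r_min;
      double logr = std::log(r);
      double g = interp_logr(g_logr.begin(), g_val.begin(), ng, logr);
      double p = interp_logr(p_logr.begin(), p_val.begin(), np, logr);
      out[i] += g * p / (r * r);
    }
  }
  return out;
}
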