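#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion (noise scale s = 1)
// through the LOWER of two absorbing boundaries {0, a}, start point w*a,
// evaluated at decision time t (already shifted by the non-decision time).
// Dual-series representation with the standard small-time/large-time switch:
// the number of terms needed for absolute error <= err is computed for both
// expansions and the cheaper one is used.

static double ftt01w(double tt, double w, double err) {
  // density of normalized time tt = t / a^2 for unit boundary, zero drift
  double kl, ks;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  double p = 0.0;
  if (ks < kl) {            // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; k++) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {                  // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

static double wfpt_lower_raw(double t, double v, double a, double w,
                             double err) {
  if (t <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return 0.0;
  double tt = t / (a * a);
  double p = ftt01w(tt, w, err);
  double f = p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
  return f > 0.0 ? f : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_wfpt_density(NumericVector t, double a, double v,
                               double t0, double w, int upper,
                               double err = 1e-7) {
  int n = t.size();
  NumericVector out(n);
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  for (int i = 0; i < n; i++) {
    double td = t[i] - t0;
    out[i] = (td > 0.0) ? wfpt_lower_raw(td, vv, a, ww, err) : 0.0;
  }
  return out;
}

// Summed log-likelihood of (rt, boundary) pairs under the
// 0.95 * WFPT + 0.05 * uniform contaminant mixture. Parameter vectors are
// per-trial (length n) so condition-dependent parameterizations resolve in R.
// The uniform contaminant spreads over (0, max_rt] split evenly across the
// two boundaries.
// [[Rcpp::export]]
double cpp_ddm_loglik(NumericVector rt, IntegerVector upper,
                      NumericVector a, NumericVector v, NumericVector t0,
                      double outlier_frac, double max_rt,
                      double err = 1e-7) {
  int n = rt.size();
  double ll = 0.0;
  double unif = (max_rt > 0.0) ? 0.5 / max_rt : 0.0;
  for (int i = 0; i < n; i++) {
    if (a[i] <= 0.0 || t0[i] < 0.0) return R_NegInf;
    double vv = upper[i] ? -v[i] : v[i];
    double ww = upper[i] ? 0.5 : 0.5;  // fixed unbiased start point
    double td = rt[i] - t0[i];
    double f = (td > 0.0) ? wfpt_lower_raw(td, vv, a[i], ww, err) : 0.0;
    double dens = (1.0 - outlier_frac) * f + outlier_frac * unif;
    if (dens <= 0.0 || !R_finite(dens)) return R_NegInf;
    ll += std::log(dens);
  }
  return ll;
}

// Euler-Maruyama simulation of the diffusion; returns rt (s, including t0)
// and boundary (1 = upper). Walks not absorbed by max_t are returned with
// rt = NA and boundary = NA. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
DataFrame cpp_simulate_ddm(int n, double a, double v, double t0, double w,
                           double dt, double max_t) {
  NumericVector rt(n);
  IntegerVector up(n);
  double sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; i++) {
    double x = w * a;
    double t = 0.0;
    bool done = false;
    while (t < max_t) {
      x += v * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { rt[i] = t + t0; up[i] = 1; done = true; break; }
      if (x <= 0.0) { rt[i] = t + t0; up[i] = 0; done = true; break; }
    }
    if (!done) { rt[i] = NA_REAL; up[i] = NA_INTEGER; }
  }
  return DataFrame::create(_["rt"] = rt, _["upper"] = up);
}
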