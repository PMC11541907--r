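#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Golden-section minimization of the exponential-decay least squares
// objective sum_i (r_i - exp(-k t_i))^2 over k in [0, k_max], per row of a
// ratio matrix. The objective is smooth and unimodal in k for decaying
// series; tolerance 1e-10 matches the R-level optimizer contract.

static double sse(const double *r, const double *t, int m, double k) {
  double s = 0.0;
  for (int i = 0; i < m; ++i) {
    double d = r[i] - std::exp(-k * t[i]);
    s += d * d;
  }
  return s;
}

// [[Rcpp::export(name = ".fit_decay_cpp")]]
NumericVector fit_decay_cpp(NumericMatrix R, NumericVector tp,
                            double k_max) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  const int n = R.nrow(), m = R.ncol();
  NumericVector out(n, NA_REAL);
  std::vector<double> r(m), t(m);
  for (int i = 0; i < m; ++i) t[i] = tp[i];
  for (int v = 0; v < n; ++v) {
    bool ok = true;
    for (int i = 0; i < m; ++i) {
      r[i] = R(v, i);
      if (!std::isfinite(r[i])) { ok = false; break; }
    }
    if (!ok) continue;
    double a = 0.0, b = k_max;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double fc = sse(r.data(), t.data(), m, c);
    double fd = sse(r.data(), t.data(), m, d);
    while (b - a > 1e-10) {
      if (fc < fd) {
        b = d; d = c; fd = fc;
        c = b - gr * (b - a);
        fc = sse(r.data(), t.data(), m, c);
      } else {
        a = c; c = d; fc = fd;
        d = a + gr * (b - a);
        fd = sse(r.data(), t.data(), m, d);
      }
    }
    double k = (a + b) / 2.0;
    if (sse(r.data(), t.data(), m, 0.0) <= sse(r.data(), t.data(), m, k))
      k = 0.0;
    out[v] = k;
  }
  return out;
}
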