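#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for sum (y - b - Xw)^2 + lambda * sum |w|,
// bias unpenalized. The residual vector is kept in sync so each coordinate
// update is O(n).
// [[Rcpp::export(name = ".lasso_cd_core")]]
List lasso_cd_core(NumericMatrix X, NumericVector y, double lambda,
                   NumericVector w_init, double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> ss(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    ss[j] = s;
  }
  std::vector<double> r(n);
  double b;
  {
    std::vector<double> xw(n, 0.0);
    for (int j = 0; j < p; ++j) {
      if (w[j] != 0.0)
        for (int i = 0; i < n; ++i) xw[i] += X(i, j) * w[j];
    }
    double s = 0;
    for (int i = 0; i < n; ++i) s += y[i] - xw[i];
    b = s / n;
    for (int i = 0; i < n; ++i) r[i] = y[i] - xw[i] - b;
  }
  bool converged = false;
  int sweep = 0;
  while (sweep < max_sweeps) {
    ++sweep;
    double delta_max = 0;
    for (int j = 0; j < p; ++j) {
      double rho = 0;
      for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
      const double z = 2 * (rho + ss[j] * w[j]);
      double wn = 0;
      if (z > lambda) wn = (z - lambda) / (2 * ss[j]);
      else if (z < -lambda) wn = (z + lambda) / (2 * ss[j]);
      if (wn != w[j]) {
        const double d = wn - w[j];
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        const double ad = std::fabs(d);
        if (ad > delta_max) delta_max = ad;
        w[j] = wn;
      }
    }
    double ms = 0;
    for (int i = 0; i < n; ++i) ms += r[i];
    ms /= n;
    if (ms != 0) {
      b += ms;
      for (int i = 0; i < n; ++i) r[i] -= ms;
      const double am = std::fabs(ms);
      if (am > delta_max) delta_max = am;
    }
    if (delta_max < tol) { converged = true; break; }
  }
  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["bias"] = b, _["sweeps"] = sweep,
                      _["converged"] = converged);
}
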