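#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) soft-margin linear SVM:
//   min_w  0.5*||w||^2 + C * sum_i max(0, 1 - y_i * w.x_i)
// following the shrinking-free form of Hsieh et al. (2008). The coordinate
// order is fixed, so the solver is fully deterministic for a given input.
// A bias term is obtained by augmenting X with a constant column (caller).
// [[Rcpp::export]]
NumericVector svm_dcd(NumericMatrix X, NumericVector y, double C,
                      int max_epochs, double tol) {
  const int n = X.nrow(), d = X.ncol();
  // row-major copy: sample i occupies a contiguous block
  std::vector<double> Xr((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      Xr[(size_t)i * d + j] = X(i, j);
  std::vector<double> w(d, 0.0), alpha(n, 0.0), Q(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = &Xr[(size_t)i * d];
    double s = 0;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    Q[i] = s;
  }
  for (int ep = 0; ep < max_epochs; ++ep) {
    double max_pg = 0;
    for (int i = 0; i < n; ++i) {
      const double *xi = &Xr[(size_t)i * d];
      double G = 0;
      for (int j = 0; j < d; ++j) G += w[j] * xi[j];
      G = y[i] * G - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        double old = alpha[i];
        double q = Q[i] > 0 ? Q[i] : 1e-12;
        double a = alpha[i] - G / q;
        alpha[i] = std::min(std::max(a, 0.0), C);
        double delta = (alpha[i] - old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
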