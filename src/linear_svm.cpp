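#include <Rcpp.h>
using namespace Rcpp;

// L2-regularized L1-loss linear SVM trained by dual coordinate descent
// (the liblinear algorithm). Deterministic: samples are visited in a fixed
// cyclic order, so repeated calls on identical input give identical weights.
// The bias is handled by augmenting every sample with a constant feature.
//
// Xt: d x n matrix (samples in columns, for contiguous access);
// y: +1/-1 labels; c_pos/c_neg: per-class C.
// Returns the weight vector of length d (bias component dropped).
// [[Rcpp::export(name = ".svm_dcd_weights")]]
NumericVector svm_dcd_weights(NumericMatrix Xt, NumericVector y,
                              double c_pos, double c_neg,
                              int max_epochs = 60, double tol = 1e-3) {
  const int d = Xt.nrow();
  const int n = Xt.ncol();
  const double bias = 1.0;
  const double *X = Xt.begin();

  std::vector<double> w(d + 1, 0.0);
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * d;
    double s = bias * bias;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *xi = X + (size_t)i * d;
      const double yi = y[i];
      const double Ci = yi > 0 ? c_pos : c_neg;
      double wx = w[d] * bias;
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      const double G = yi * wx - 1.0;

      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= Ci && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (PG == 0.0) continue;

      const double old = alpha[i];
      double a = old - G / qii[i];
      if (a < 0.0) a = 0.0;
      if (a > Ci) a = Ci;
      const double delta = (a - old) * yi;
      if (delta != 0.0) {
        alpha[i] = a;
        for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
        w[d] += delta * bias;
      }
    }
    if (max_viol < tol) break;
  }

  NumericVector out(d);
  for (int j = 0; j < d; ++j) out[j] = w[j];
  return out;
}
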