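#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// Batch training of a k-h-1 multilayer perceptron (logistic hidden and
// output units) on case-weighted binary cross-entropy with L2 weight decay,
// using the iRprop- update rule. Resilient propagation needs no learning
// rate tuning and its per-epoch cost is linear in the number of weights,
// which keeps the hidden-layer sweep up to h = k tractable.
//
// Weight layout matches nnet: for each hidden unit j the block
// (bias, w_1j..w_kj), then the output block (bias, v_1..v_h).
// [[Rcpp::export]]
NumericVector mlp_train_cpp(NumericMatrix X, NumericVector y,
                            NumericVector casew, int h,
                            NumericVector wts0, int epochs, double decay) {
  const int n = X.nrow(), k = X.ncol();
  const int nw = (k + 1) * h + h + 1;
  std::vector<double> w(wts0.begin(), wts0.end());
  if ((int)w.size() != nw) stop("weight vector length mismatch");

  std::vector<double> grad(nw), prev(nw, 0.0), step(nw, 0.01);
  std::vector<double> z(h), dz(h);
  const double inc = 1.2, dec = 0.5, smin = 1e-9, smax = 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      // forward
      for (int j = 0; j < h; ++j) {
        const double* wj = &w[j * (k + 1)];
        double a = wj[0];
        for (int l = 0; l < k; ++l) a += wj[l + 1] * X(i, l);
        z[j] = logistic(a);
      }
      const double* v = &w[(k + 1) * h];
      double o = v[0];
      for (int j = 0; j < h; ++j) o += v[j + 1] * z[j];
      o = logistic(o);
      // backward (cross-entropy + logistic output: delta = o - y)
      double err = (o - y[i]) * casew[i];
      grad[(k + 1) * h] += err;
      for (int j = 0; j < h; ++j) {
        grad[(k + 1) * h + 1 + j] += err * z[j];
        dz[j] = err * v[j + 1] * z[j] * (1.0 - z[j]);
      }
      for (int j = 0; j < h; ++j) {
        double* gj = &grad[j * (k + 1)];
        gj[0] += dz[j];
        for (int l = 0; l < k; ++l) gj[l + 1] += dz[j] * X(i, l);
      }
    }
    // iRprop- update with decay
    for (int m = 0; m < nw; ++m) {
      double g = grad[m] + decay * w[m];
      double s = g * prev[m];
      if (s > 0) {
        step[m] = std::min(step[m] * inc, smax);
      } else if (s < 0) {
        step[m] = std::max(step[m] * dec, smin);
        g = 0.0;  // iRprop-: skip update after a sign change
      }
      if (g > 0) w[m] -= step[m];
      else if (g < 0) w[m] += step[m];
      prev[m] = g;
    }
  }
  return NumericVector(w.begin(), w.end());
}
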