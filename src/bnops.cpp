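// Fused column-wise kernels for the network hot path: bias add, per-column
// scale/shift, and single-pass batch-normalisation forward/backward. These
// replace repeated R-level temporaries on (batch*vertices) x features
// matrices with one C pass each.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".gmColAdd")]]
NumericMatrix gm_col_add(NumericMatrix x, NumericVector v) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    double vj = v[j];
    const double* xi = &x(0, j);
    double* oi = &out(0, j);
    for (int i = 0; i < n; ++i) oi[i] = xi[i] + vj;
  }
  return out;
}

// y[, j] = x[, j] * scale[j] + shift[j]
// [[Rcpp::export(name = ".gmScaleShift")]]
NumericMatrix gm_scale_shift(NumericMatrix x, NumericVector scale,
                             NumericVector shift) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    double s = scale[j], t = shift[j];
    const double* xi = &x(0, j);
    double* oi = &out(0, j);
    for (int i = 0; i < n; ++i) oi[i] = xi[i] * s + t;
  }
  return out;
}

// Batch-norm training forward: per-column mean/biased variance over all rows,
// xhat = (x - mu)/sqrt(var + eps), y = gamma * xhat + beta.
// [[Rcpp::export(name = ".gmBnTrainForward")]]
List gm_bn_train_forward(NumericMatrix x, NumericVector gamma,
                         NumericVector beta, double eps) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix xhat(n, p), y(n, p);
  NumericVector mu(p), var(p), sd(p);
  for (int j = 0; j < p; ++j) {
    const double* xi = &x(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xi[i];
    double m = s / n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { double d = xi[i] - m; v += d * d; }
    v /= n;
    double sdj = std::sqrt(v + eps);
    double g = gamma[j], b = beta[j];
    double* xh = &xhat(0, j);
    double* yj = &y(0, j);
    for (int i = 0; i < n; ++i) {
      double h = (xi[i] - m) / sdj;
      xh[i] = h;
      yj[i] = g * h + b;
    }
    mu[j] = m; var[j] = v; sd[j] = sdj;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sd"] = sd,
                      _["mu"] = mu, _["var"] = var);
}

// Batch-norm training backward from cached xhat and sd.
// [[Rcpp::export(name = ".gmBnTrainBackward")]]
List gm_bn_train_backward(NumericMatrix dy, NumericVector gamma,
                          NumericMatrix xhat, NumericVector sd) {
  int n = dy.nrow(), p = dy.ncol();
  NumericMatrix dx(n, p);
  NumericVector dgamma(p), dbeta(p);
  for (int j = 0; j < p; ++j) {
    const double* dyj = &dy(0, j);
    const double* xh = &xhat(0, j);
    double g = gamma[j], sdj = sd[j];
    double s1 = 0.0, s2 = 0.0, db = 0.0, dg = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = dyj[i] * g;
      s1 += d;
      s2 += d * xh[i];
      db += dyj[i];
      dg += dyj[i] * xh[i];
    }
    double m1 = s1 / n, m2 = s2 / n;
    double* dxj = &dx(0, j);
    for (int i = 0; i < n; ++i)
      dxj[i] = (dyj[i] * g - m1 - xh[i] * m2) / sdj;
    dgamma[j] = dg; dbeta[j] = db;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ReLU forward returning both output and mask in one pass.
// [[Rcpp::export(name = ".gmReluForward")]]
List gm_relu_forward(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  LogicalMatrix mask(n, p);
  for (int j = 0; j < p; ++j) {
    const double* xi = &x(0, j);
    double* oi = &out(0, j);
    int* mi = &mask(0, j);
    for (int i = 0; i < n; ++i) {
      bool pos = xi[i] > 0.0;
      mi[i] = pos;
      oi[i] = pos ? xi[i] : 0.0;
    }
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}
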