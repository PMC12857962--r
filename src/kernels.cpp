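// Hot numerical kernels for the autodiff engine. Each op has a forward
// that may return cached intermediates and a backward that consumes
// them; the R wrappers in R/autodiff.R and R/nn-ops.R own the tape
// bookkeeping. Plain Rcpp; BLAS-sized matrix products stay in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GELU_C0 = 0.7978845608028654; // sqrt(2/pi)

// [[Rcpp::export]]
List cpp_gelu_fwd(NumericMatrix X) {
  R_xlen_t n = X.size();
  NumericMatrix Y(X.nrow(), X.ncol());
  NumericMatrix TH(X.nrow(), X.ncol());
  const double *x = X.begin();
  double *y = Y.begin();
  double *th = TH.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    double t = std::tanh(GELU_C0 * (v + 0.044715 * v * v * v));
    th[i] = t;
    y[i] = 0.5 * v * (1.0 + t);
  }
  return List::create(_["Y"] = Y, _["TH"] = TH);
}

// [[Rcpp::export]]
NumericMatrix cpp_gelu_bwd(NumericMatrix X, NumericMatrix TH,
                           NumericMatrix G) {
  R_xlen_t n = X.size();
  NumericMatrix D(X.nrow(), X.ncol());
  const double *x = X.begin(), *th = TH.begin(), *g = G.begin();
  double *d = D.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i], t = th[i];
    double dinner = GELU_C0 * (1.0 + 3.0 * 0.044715 * v * v);
    d[i] = g[i] * (0.5 * (1.0 + t) + 0.5 * v * (1.0 - t * t) * dinner);
  }
  return D;
}

// [[Rcpp::export]]
List cpp_layernorm_fwd(NumericMatrix X, NumericVector gain,
                       NumericVector bias, double eps) {
  int n = X.nrow(), d = X.ncol();
  NumericMatrix Y(n, d), XN(n, d);
  NumericVector istd(n);
  std::vector<double> mu(n, 0.0), va(n, 0.0);
  const double *x = X.begin();
  for (int j = 0; j < d; ++j) {
    const double *col = x + (size_t)j * n;
    for (int i = 0; i < n; ++i) mu[i] += col[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= d;
  for (int j = 0; j < d; ++j) {
    const double *col = x + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double c = col[i] - mu[i];
      va[i] += c * c;
    }
  }
  for (int i = 0; i < n; ++i) istd[i] = 1.0 / std::sqrt(va[i] / d + eps);
  double *yn = XN.begin(), *y = Y.begin();
  for (int j = 0; j < d; ++j) {
    const double *col = x + (size_t)j * n;
    double *cn = yn + (size_t)j * n, *cy = y + (size_t)j * n;
    double gj = gain[j], bj = bias[j];
    for (int i = 0; i < n; ++i) {
      double v = (col[i] - mu[i]) * istd[i];
      cn[i] = v;
      cy[i] = v * gj + bj;
    }
  }
  return List::create(_["Y"] = Y, _["XN"] = XN, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_layernorm_bwd(NumericMatrix XN, NumericVector istd,
                       NumericVector gain, NumericMatrix G) {
  int n = XN.nrow(), d = XN.ncol();
  NumericMatrix DX(n, d);
  NumericVector dGain(d), dBias(d);
  std::vector<double> rs1(n, 0.0), rs2(n, 0.0);
  const double *xn = XN.begin(), *g = G.begin();
  for (int j = 0; j < d; ++j) {
    const double *cg = g + (size_t)j * n, *cn = xn + (size_t)j * n;
    double gj = gain[j];
    double a = 0, bsum = 0;
    for (int i = 0; i < n; ++i) {
      double dxn = cg[i] * gj;
      rs1[i] += dxn;
      rs2[i] += dxn * cn[i];
      a += cg[i] * cn[i];
      bsum += cg[i];
    }
    dGain[j] = a;
    dBias[j] = bsum;
  }
  for (int i = 0; i < n; ++i) { rs1[i] /= d; rs2[i] /= d; }
  double *dx = DX.begin();
  for (int j = 0; j < d; ++j) {
    const double *cg = g + (size_t)j * n, *cn = xn + (size_t)j * n;
    double *cd = dx + (size_t)j * n;
    double gj = gain[j];
    for (int i = 0; i < n; ++i) {
      cd[i] = istd[i] * (cg[i] * gj - rs1[i] - cn[i] * rs2[i]);
    }
  }
  return List::create(_["dX"] = DX, _["dGain"] = dGain,
                      _["dBias"] = dBias);
}

// [[Rcpp::export]]
NumericMatrix cpp_softmax_rows(NumericMatrix Z) {
  int n = Z.nrow(), d = Z.ncol();
  NumericMatrix P(n, d);
  for (int i = 0; i < n; ++i) {
    double mx = Z(i, 0);
    for (int j = 1; j < d; ++j) if (Z(i, j) > mx) mx = Z(i, j);
    double s = 0;
    for (int j = 0; j < d; ++j) {
      double e = std::exp(Z(i, j) - mx);
      P(i, j) = e;
      s += e;
    }
    for (int j = 0; j < d; ++j) P(i, j) /= s;
  }
  return P;
}

// Add a bias row to a freshly-allocated matrix, in place (the caller
// guarantees Y is not shared).
// [[Rcpp::export]]
NumericMatrix cpp_add_bias_inplace(NumericMatrix Y, NumericVector b) {
  int n = Y.nrow(), d = Y.ncol();
  double *y = Y.begin();
  for (int j = 0; j < d; ++j) {
    double bj = b[j];
    double *col = y + (size_t)j * n;
    for (int i = 0; i < n; ++i) col[i] += bj;
  }
  return Y;
}
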