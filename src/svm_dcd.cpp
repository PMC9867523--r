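#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SMO solver for the binary soft-margin SVM dual
//   min_a 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,
//   Q_ij = y_i y_j K(x_i, x_j)
// with maximal-violating-pair working-set selection and an explicit bias
// recovered from the KKT conditions. Kernels: 0 = linear, 1 = RBF.
// Desk-scale problems, so the kernel matrix is precomputed.

static inline double dot(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += a[k] * b[k];
  return s;
}

// [[Rcpp::export]]
List svm_smo_train(NumericMatrix X, NumericVector y, double C,
                   int kernel, double gamma,
                   int max_iter = 200000, double eps = 1e-3) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> Xr((size_t)n * d), sq(n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xr[(size_t)i * d + k] = X(i, k);
  if (kernel == 1)
    for (int i = 0; i < n; ++i)
      sq[i] = dot(&Xr[(size_t)i * d], &Xr[(size_t)i * d], d);

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double ip = dot(&Xr[(size_t)i * d], &Xr[(size_t)j * d], d);
      double kij = (kernel == 0) ? ip
                 : std::exp(-gamma * (sq[i] + sq[j] - 2.0 * ip));
      K[(size_t)i * n + j] = kij;
      K[(size_t)j * n + i] = kij;
    }
  }

  NumericVector alpha(n);
  std::vector<double> E(n);  // E_t = f(x_t) - y_t, f without bias
  for (int t = 0; t < n; ++t) E[t] = -y[t];

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: i maximises -E over I_up, j minimises over
    // I_low
    int i = -1, j = -1;
    double up = -1e300, lo = 1e300;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && -E[t] > up) { up = -E[t]; i = t; }
      if (in_lo && -E[t] < lo) { lo = -E[t]; j = t; }
    }
    if (i < 0 || j < 0 || up - lo < eps) break;

    const double yi = y[i], yj = y[j];
    const double kii = K[(size_t)i * n + i], kjj = K[(size_t)j * n + j],
                 kij = K[(size_t)i * n + j];
    double eta = kii + kjj - 2.0 * kij;
    if (eta <= 1e-12) eta = 1e-12;
    double L, H;
    if (yi != yj) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    double aj_new = alpha[j] + yj * (E[i] - E[j]) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    const double dj = aj_new - alpha[j];
    if (std::fabs(dj) < 1e-15) break;  // numerically stuck at optimum
    const double di = -yi * yj * dj;
    alpha[i] += di;
    alpha[j] = aj_new;
    const double ci = di * yi, cj = dj * yj;
    const double *Ki = &K[(size_t)i * n], *Kj = &K[(size_t)j * n];
    for (int t = 0; t < n; ++t) E[t] += ci * Ki[t] + cj * Kj[t];
  }

  // bias from free support vectors, midpoint fallback
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 * C && alpha[t] < C * (1 - 1e-12)) {
      bsum += -E[t];
      ++nfree;
    }
  }
  double b;
  if (nfree > 0) {
    b = bsum / nfree;
  } else {
    double up = -1e300, lo = 1e300;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_lo = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (in_up && -E[t] > up) up = -E[t];
      if (in_lo && -E[t] < lo) lo = -E[t];
    }
    b = (up + lo) / 2.0;
  }
  return List::create(_["alpha"] = alpha, _["b"] = b, _["iter"] = iter);
}

// Decision values f(q) = sum_i coef_i K(q, x_i) + b, coef_i = alpha_i y_i
// [[Rcpp::export]]
NumericVector svm_decision(NumericMatrix Xsv, NumericVector coef, double b,
                           NumericMatrix Q, int kernel, double gamma) {
  const int n = Xsv.nrow(), d = Xsv.ncol(), m = Q.nrow();
  std::vector<double> Xr((size_t)n * d), Qr((size_t)m * d), sq(n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xr[(size_t)i * d + k] = Xsv(i, k);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) Qr[(size_t)i * d + k] = Q(i, k);
  if (kernel == 1)
    for (int i = 0; i < n; ++i)
      sq[i] = dot(&Xr[(size_t)i * d], &Xr[(size_t)i * d], d);
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    const double* xq = &Qr[(size_t)q * d];
    double sqq = (kernel == 1) ? dot(xq, xq, d) : 0.0;
    double f = b;
    for (int i = 0; i < n; ++i) {
      double ip = dot(&Xr[(size_t)i * d], xq, d);
      double kiq = (kernel == 0) ? ip
                 : std::exp(-gamma * (sq[i] + sqq - 2.0 * ip));
      f += coef[i] * kiq;
    }
    out[q] = f;
  }
  return out;
}
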