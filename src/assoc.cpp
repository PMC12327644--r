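// Association and LD kernels operating directly on integer dosage matrices,
// scaling columns on the fly so the n x m double design is never materialised
// (at UKB-like n that matrix would not fit in memory).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-column mean and sd (denominator n) of an integer dosage matrix.
// [[Rcpp::export]]
List geno_col_stats_cpp(IntegerMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  NumericVector mean(m), sd(m);
  const int* g = INTEGER(G);
  for (int j = 0; j < m; ++j) {
    const int* col = g + (std::size_t)j * n;
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) { s += col[i]; ss += (double)col[i] * col[i]; }
    double mu = s / n;
    mean[j] = mu;
    double v = ss / n - mu * mu;
    sd[j] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Single-SNP OLS of y on the scaled column (x - center_j) / scale_j, with
// intercept. Returns slope, SE and the centered sums needed downstream.
// [[Rcpp::export]]
List gwas_linear_geno_cpp(IntegerMatrix G, NumericVector y,
                          NumericVector center, NumericVector scale) {
  const int n = G.nrow(), m = G.ncol();
  const int* g = INTEGER(G);
  double sy = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) { sy += y[i]; syy += y[i] * y[i]; }
  const double ybar = sy / n;
  const double syy_c = syy - n * ybar * ybar;
  NumericVector beta(m), se(m);
  for (int j = 0; j < m; ++j) {
    const int* col = g + (std::size_t)j * n;
    double sx = 0.0, sxx = 0.0, sxy = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = col[i];
      sx += x; sxx += x * x; sxy += x * y[i];
    }
    const double xbar = sx / n;
    const double sxx_c = sxx - n * xbar * xbar;   // centered about sample mean
    const double sxy_c = sxy - n * xbar * ybar;
    if (sxx_c <= 0.0 || scale[j] <= 0.0) { beta[j] = NA_REAL; se[j] = NA_REAL; continue; }
    // w = (x - center)/scale; slope uses centered x regardless of 'center'
    const double ww = sxx_c / (scale[j] * scale[j]);
    const double wy = sxy_c / scale[j];
    const double b = wy / ww;
    double sse = syy_c - b * wy;
    if (sse < 0) sse = 0;
    beta[j] = b;
    se[j] = std::sqrt(sse / (n - 2) / ww);
  }
  return List::create(_["beta"] = beta, _["se"] = se);
}

// Dense Pearson correlation of dosage columns, accumulated over row chunks so
// peak extra memory is chunk x m doubles. center/scale are the per-column
// sample mean and sd(denominator n), so the result has unit diagonal.
// [[Rcpp::export]]
NumericMatrix ld_geno_dense_cpp(IntegerMatrix G, NumericVector center,
                                NumericVector scale, int chunk) {
  const int n = G.nrow(), m = G.ncol();
  const int* g = INTEGER(G);
  arma::mat B(m, m, arma::fill::zeros);
  arma::mat X;
  for (int r0 = 0; r0 < n; r0 += chunk) {
    const int nr = std::min(chunk, n - r0);
    X.set_size(nr, m);
    for (int j = 0; j < m; ++j) {
      const int* col = g + (std::size_t)j * n + r0;
      const double c = center[j], s = 1.0 / scale[j];
      double* xj = X.colptr(j);
      for (int i = 0; i < nr; ++i) xj[i] = (col[i] - c) * s;
    }
    B += X.t() * X;
  }
  B /= (double)n;
  return wrap(B);
}

// Banded correlations: band(k+1, j) holds r between variants j and j+k,
// k = 0..hb (so the first band row is the unit diagonal).
// [[Rcpp::export]]
NumericMatrix ld_geno_band_cpp(IntegerMatrix G, NumericVector center,
                               NumericVector scale, int hb, int chunk) {
  const int n = G.nrow(), m = G.ncol();
  const int* g = INTEGER(G);
  NumericMatrix band(hb + 1, m);
  arma::mat X;
  for (int r0 = 0; r0 < n; r0 += chunk) {
    const int nr = std::min(chunk, n - r0);
    X.set_size(nr, m);
    for (int j = 0; j < m; ++j) {
      const int* col = g + (std::size_t)j * n + r0;
      const double c = center[j], s = 1.0 / scale[j];
      double* xj = X.colptr(j);
      for (int i = 0; i < nr; ++i) xj[i] = (col[i] - c) * s;
    }
    for (int j = 0; j < m; ++j) {
      const int kmax = std::min(hb, m - 1 - j);
      for (int k = 0; k <= kmax; ++k)
        band(k, j) += arma::dot(X.col(j), X.col(j + k));
    }
  }
  for (int j = 0; j < m; ++j)
    for (int k = 0; k <= hb; ++k) band(k, j) /= (double)n;
  return band;
}

// Per-variant logistic regression (intercept + scaled dosage) by
// Newton-Raphson; Wald SE. Mirrors PLINK 1.9's single-SNP logistic model.
// [[Rcpp::export]]
List gwas_logistic_geno_cpp(IntegerMatrix G, IntegerVector y,
                            NumericVector center, NumericVector scale,
                            int max_iter, double tol) {
  const int n = G.nrow(), m = G.ncol();
  const int* g = INTEGER(G);
  NumericVector beta(m), se(m);
  LogicalVector conv(m), sep(m);
  std::vector<double> w(n);
  for (int j = 0; j < m; ++j) {
    const int* col = g + (std::size_t)j * n;
    const double c = center[j], s = 1.0 / scale[j];
    for (int i = 0; i < n; ++i) w[i] = (col[i] - c) * s;
    double b0 = 0.0, b1 = 0.0;
    bool converged = false, separated = false;
    for (int it = 0; it < max_iter; ++it) {
      double S0 = 0, S1 = 0, S2 = 0, g0 = 0, g1 = 0;
      for (int i = 0; i < n; ++i) {
        const double eta = b0 + b1 * w[i];
        const double p = 1.0 / (1.0 + std::exp(-eta));
        const double v = p * (1.0 - p);
        S0 += v; S1 += v * w[i]; S2 += v * w[i] * w[i];
        const double r = y[i] - p;
        g0 += r; g1 += r * w[i];
      }
      const double det = S0 * S2 - S1 * S1;
      if (det <= 1e-12 || !std::isfinite(det)) { separated = true; break; }
      const double d0 = (S2 * g0 - S1 * g1) / det;
      const double d1 = (S0 * g1 - S1 * g0) / det;
      b0 += d0; b1 += d1;
      if (std::fabs(b1) > 15.0) { separated = true; break; }
      if (std::fabs(d0) < tol && std::fabs(d1) < tol) {
        converged = true;
        se[j] = std::sqrt(S0 / det);
        break;
      }
    }
    beta[j] = b1;
    conv[j] = converged;
    sep[j] = separated;
    if (!converged) se[j] = NA_REAL;
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["converged"] = conv, _["separated"] = sep);
}

// Weighted sum of scaled dosage columns (a polygenic score / genetic value):
// g[i] = sum_j w_j * (G[i, idx_j] - center_j) / scale_j, streamed over the
// integer matrix so no n x k double copy is ever made.
// [[Rcpp::export]]
NumericVector geno_weighted_sum_cpp(IntegerMatrix G, IntegerVector idx0,
                                    NumericVector w, NumericVector center,
                                    NumericVector scale) {
  const int n = G.nrow(), k = idx0.size();
  const int* g = INTEGER(G);
  NumericVector out(n);
  double* o = REAL(out);
  double off = 0.0;
  for (int jj = 0; jj < k; ++jj) {
    const int j = idx0[jj];
    const double a = w[jj] / scale[jj];
    off += a * center[jj];
    const int* col = g + (std::size_t)j * n;
    for (int i = 0; i < n; ++i) o[i] += a * col[i];
  }
  for (int i = 0; i < n; ++i) o[i] -= off;
  return out;
}

// Per-column mean and sd (denominator n) restricted to a column subset.
// [[Rcpp::export]]
List geno_col_stats_idx_cpp(IntegerMatrix G, IntegerVector idx0) {
  const int n = G.nrow(), k = idx0.size();
  const int* g = INTEGER(G);
  NumericVector mean(k), sd(k);
  for (int jj = 0; jj < k; ++jj) {
    const int* col = g + (std::size_t)idx0[jj] * n;
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) { s += col[i]; ss += (double)col[i] * col[i]; }
    const double mu = s / n;
    mean[jj] = mu;
    const double v = ss / n - mu * mu;
    sd[jj] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
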