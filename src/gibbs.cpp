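// Single-site Gibbs sampler for Bayesian linear regression on summary
// statistics: mixture prior over SNP effects with a point mass at zero plus
// Gaussian classes with variances gamma_c * sigma_b2 (BayesC is the 2-class
// case gamma = (0, 1)). Operates on reconstructed X'X / X'y with
// right-hand-side residual updating: r = X'y - X'X b is maintained and only
// coordinates whose effect changes trigger an O(m) (or O(band)) update.
#include <Rcpp.h>
using namespace Rcpp;

static inline double inv_chisq_draw(double df, double scale_sum) {
  // scale_sum = (sum of squares + nu * S2); draw scale_sum / chisq(df)
  return scale_sum / R::rchisq(df);
}

// [[Rcpp::export]]
List blr_gibbs_cpp(NumericMatrix XtX, NumericMatrix band, bool banded, int hb,
                   NumericVector Xty, double n, double yty,
                   NumericVector gamma, NumericVector pi0,
                   bool estimate_pi, NumericVector alpha,
                   double nu_b, double s_b2, double nu_e, double s_e2,
                   bool update_sigma_b2, bool update_sigma_e2,
                   double sigma_b2_init, double sigma_e2_init,
                   int n_iter, int n_burnin, int thin) {
  const int m = Xty.size();
  const int C = gamma.size();
  std::vector<double> b(m, 0.0), r(Xty.begin(), Xty.end());
  std::vector<int> cls(m, 0);
  std::vector<double> diag(m);
  if (banded) {
    for (int i = 0; i < m; ++i) diag[i] = band(0, i);
  } else {
    for (int i = 0; i < m; ++i) diag[i] = XtX(i, i);
  }
  for (int i = 0; i < m; ++i)
    if (!(diag[i] > 0.0))
      stop("non-positive diagonal in X'X at variant %d; the LD matrix may be ill-conditioned - add a small diagonal jitter (ridge)", i + 1);

  double sigma_b2 = sigma_b2_init, sigma_e2 = sigma_e2_init;
  std::vector<double> pi(pi0.begin(), pi0.end());

  const int n_kept = (n_iter - n_burnin + thin - 1) / thin;
  NumericVector pip(m), b_mean(m);
  NumericMatrix cls_prob(m, C);
  // chain columns: sigma_b2, sigma_e2, sigma_g2, k_nonzero, pi_1..pi_C
  NumericMatrix chains(n_kept, 4 + C);
  int kept = 0, n_clamped = 0;
  std::vector<double> lp(C), pr(C);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < m; ++i) {
      const double dii = diag[i];
      const double rhs = r[i] + dii * b[i];
      lp[0] = std::log(pi[0]);
      double mx = lp[0];
      for (int c = 1; c < C; ++c) {
        const double v = gamma[c] * sigma_b2;
        const double lhs = dii + sigma_e2 / v;
        lp[c] = std::log(pi[c]) +
                0.5 * (std::log(sigma_e2) - std::log(v) - std::log(lhs)) +
                rhs * rhs / (2.0 * sigma_e2 * lhs);
        if (lp[c] > mx) mx = lp[c];
      }
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { pr[c] = std::exp(lp[c] - mx); tot += pr[c]; }
      double u = unif_rand() * tot;
      int c_new = C - 1;
      for (int c = 0; c < C; ++c) { u -= pr[c]; if (u <= 0.0) { c_new = c; break; } }
      double b_new = 0.0;
      if (c_new > 0) {
        const double v = gamma[c_new] * sigma_b2;
        const double lhs = dii + sigma_e2 / v;
        b_new = rhs / lhs + norm_rand() * std::sqrt(sigma_e2 / lhs);
      }
      const double db = b_new - b[i];
      if (db != 0.0) {
        if (banded) {
          const int kmax = std::min(hb, m - 1 - i);
          for (int k = 0; k <= kmax; ++k) r[i + k] -= band(k, i) * db;
          const int kmin = std::min(hb, i);
          for (int k = 1; k <= kmin; ++k) r[i - k] -= band(k, i - k) * db;
        } else {
          const double* col = &XtX(0, i);
          for (int j = 0; j < m; ++j) r[j] -= col[j] * db;
        }
        b[i] = b_new;
      }
      cls[i] = c_new;
    }

    // hyperparameters
    double ssb = 0.0, bXty = 0.0, br = 0.0;
    int k = 0;
    std::vector<int> counts(C, 0);
    for (int i = 0; i < m; ++i) {
      counts[cls[i]]++;
      if (cls[i] > 0) {
        ++k;
        ssb += b[i] * b[i] / gamma[cls[i]];
        bXty += b[i] * Xty[i];
        br += b[i] * r[i];
      }
    }
    const double bXtXb = bXty - br;
    if (update_sigma_b2)
      sigma_b2 = inv_chisq_draw(nu_b + k, ssb + nu_b * s_b2);
    double sse = yty - bXty - br;
    if (update_sigma_e2) {
      if (sse < 1e-8 * yty) { sse = 1e-8 * yty; ++n_clamped; }
      sigma_e2 = inv_chisq_draw(n + nu_e, sse + nu_e * s_e2);
    }
    if (estimate_pi) {
      double tot = 0.0;
      for (int c = 0; c < C; ++c) { pi[c] = R::rgamma(counts[c] + alpha[c], 1.0); tot += pi[c]; }
      for (int c = 0; c < C; ++c) pi[c] /= tot;
    }

    if (iter >= n_burnin && (iter - n_burnin) % thin == 0) {
      for (int i = 0; i < m; ++i) {
        if (cls[i] > 0) { pip[i] += 1.0; b_mean[i] += b[i]; }
        cls_prob(i, cls[i]) += 1.0;
      }
      chains(kept, 0) = sigma_b2;
      chains(kept, 1) = sigma_e2;
      chains(kept, 2) = bXtXb / n;
      chains(kept, 3) = k;
      for (int c = 0; c < C; ++c) chains(kept, 4 + c) = pi[c];
      ++kept;
    }

    // periodic refresh of r to cancel floating-point drift
    if ((iter + 1) % 500 == 0) {
      std::copy(Xty.begin(), Xty.end(), r.begin());
      for (int i = 0; i < m; ++i) {
        if (b[i] == 0.0) continue;
        const double bi = b[i];
        if (banded) {
          const int kmax = std::min(hb, m - 1 - i);
          for (int kk = 0; kk <= kmax; ++kk) r[i + kk] -= band(kk, i) * bi;
          const int kmin = std::min(hb, i);
          for (int kk = 1; kk <= kmin; ++kk) r[i - kk] -= band(kk, i - kk) * bi;
        } else {
          const double* col = &XtX(0, i);
          for (int j = 0; j < m; ++j) r[j] -= col[j] * bi;
        }
      }
    }
  }

  for (int i = 0; i < m; ++i) {
    pip[i] /= kept;
    b_mean[i] /= kept;
    for (int c = 0; c < C; ++c) cls_prob(i, c) /= kept;
  }
  return List::create(_["pip"] = pip, _["b_mean"] = b_mean,
                      _["cls_prob"] = cls_prob, _["chains"] = chains,
                      _["n_kept"] = kept, _["n_sse_clamped"] = n_clamped);
}
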