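test_that("prior constructors validate and normalise their inputs", {
  pr <- bayesr_prior()
  expect_equal(sum(pr$pi), 1)
  expect_equal(pr$pi, c(0.99, 0.06, 0.03, 0.01) / 1.09)
  expect_equal(attr(pr, "class"), "blr_prior")
  expect_error(bayesr_prior(gamma = c(0.1, 1)), "gamma")
  expect_error(bayesr_prior(pi = c(0.9, 0.1)), "equal length")
  expect_error(bayesc_prior(pi = 1.2), "pi")
  expect_error(bayesc_prior(nu_b = 2), "nu_b")
  expect_error(mcmc_options(n_iter = 100, n_burnin = 100), "n_burnin")
  pc <- bayesc_prior(pi = 0.3)
  expect_equal(pc$pi, c(0.7, 0.3))
  expect_equal(pc$gamma, c(0, 1))
})

test_that("enumeration oracle obeys exchangeability and prior domination", {
  # no signal: the Bayes factor cannot raise inclusion above the prior
  ss <- make_sumstats(beta = 0, se = 0.01, n = 10000)
  B <- ld_from_matrix(matrix(1, 1, 1), ids = ss$id)
  expect_lt(exact_posterior_oracle(ss, B, sigma_b2 = 0.01, sigma_e2 = 1, pi = 0.1),
            0.1)
  # exact duplicates get identical PIPs
  R <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  ss3 <- make_sumstats(beta = c(0.05, 0.05, 0), se = rep(0.01, 3), n = 10000)
  pip <- exact_posterior_oracle(ss3, ld_from_matrix(R, ids = ss3$id),
                                sigma_b2 = 0.01, sigma_e2 = 1, pi = 0.05)
  expect_equal(pip[1], pip[2], tolerance = 1e-12)
  expect_error(exact_posterior_oracle(XtX = diag(13), Xty = rep(0, 13),
                                      sigma_b2 = 0.01, sigma_e2 = 1, pi = 0.1),
               "m > 12")
})

test_that("Gibbs PIPs match the exact enumeration posterior (fixed hyperparameters)", {
  for (case in list(list(rho = 0.0, seed = 1), list(rho = 0.9, seed = 2))) {
    r <- make_region(n = 3000, m = 5, rho = case$rho, b = 0.1, seed = case$seed)
    pip_ex <- exact_posterior_oracle(r$ss, r$B, sigma_b2 = 0.01, sigma_e2 = 1,
                                     pi = 0.1)
    fit <- blr_gibbs(reconstruct_suffstats(r$ss, r$B),
                     prior = bayesc_prior(pi = 0.1, estimate_pi = FALSE,
                                          sigma_b2_init = 0.01),
                     opts = mcmc_options(n_iter = 30000, n_burnin = 2000,
                                         seed = case$seed),
                     update_sigma_b2 = FALSE, update_sigma_e2 = FALSE)
    expect_lt(max(abs(fit$pip - pip_ex)), 0.02)
  }
})

test_that("a single strong variant reaches the closed-form two-model posterior", {
  # z = 10 at n = 10,000: beta = 10/sqrt(n), se = 1/sqrt(n)
  n <- 10000
  ss <- make_sumstats(beta = 10 / sqrt(n), se = 1 / sqrt(n), n = n)
  B <- ld_from_matrix(matrix(1, 1, 1), ids = ss$id)
  pip_exact <- exact_posterior_oracle(ss, B, sigma_b2 = 0.01, sigma_e2 = 1,
                                      pi = 0.01)
  fit <- fit_blr(ss, B, bayesc_prior(pi = 0.01, estimate_pi = FALSE,
                                     sigma_b2_init = 0.01),
                 mcmc_options(n_iter = 20000, n_burnin = 2000, seed = 4))
  expect_gt(fit$pip, 0.99)
  expect_lt(abs(fit$pip - pip_exact), 0.02)
})

test_that("perfectly correlated pair shares the exact inclusion mass", {
  g <- simulate_genotypes(5000, 3, maf_range = c(0.2, 0.4), ld_rho = 0, seed = 9)
  g$counts[, 2] <- g$counts[, 1]
  W <- scale_genotypes(g)
  set.seed(10)
  y <- 0.08 * W$W[, 1] + rnorm(5000)
  ss <- gwas_linear(W, y)
  B <- compute_ld(W)
  pe <- exact_posterior_oracle(ss, B, sigma_b2 = 0.01, sigma_e2 = 1, pi = 0.1)
  fit <- blr_gibbs(reconstruct_suffstats(ss, B),
                   prior = bayesc_prior(pi = 0.1, estimate_pi = FALSE,
                                        sigma_b2_init = 0.01),
                   opts = mcmc_options(n_iter = 50000, n_burnin = 2000, seed = 1),
                   update_sigma_b2 = FALSE, update_sigma_e2 = FALSE)
  expect_lt(abs((fit$pip[1] + fit$pip[2]) - (pe[1] + pe[2])), 0.03)
  expect_lt(abs(fit$pip[1] - fit$pip[2]), 0.05)  # exchangeable duplicates
})

test_that("degenerate all-null prior keeps every effect at zero", {
  r <- make_region(n = 1000, m = 10, b = 0.2, seed = 12)
  fit <- fit_blr(r$ss, r$B, bayesc_prior(pi = 0, estimate_pi = FALSE),
                 mcmc_options(n_iter = 2000, n_burnin = 200, seed = 1))
  expect_equal(fit$pip, rep(0, 10))
  expect_equal(fit$b_mean, rep(0, 10))
})

test_that("BayesR with gamma (0,1) reproduces BayesC on shared instances", {
  r <- make_region(n = 4000, m = 50, rho = 0.7, b = 0.12, seed = 3)
  fc <- fit_blr(r$ss, r$B, bayesc_prior(pi = 0.05),
                mcmc_options(15000, 2000, seed = 5))
  fr <- fit_blr(r$ss, r$B,
                bayesr_prior(gamma = c(0, 1), pi = c(0.95, 0.05), alpha = c(1, 1)),
                mcmc_options(15000, 2000, seed = 6))
  expect_lt(max(abs(fc$pip - fr$pip)), 0.02)
})

test_that("summary-statistic fit equals an individual-level fit with in-sample LD", {
  r <- make_region(n = 2500, m = 60, rho = 0.6, b = 0.1, seed = 21)
  opts <- mcmc_options(10000, 1000, seed = 7)
  f_ss <- fit_blr(r$ss, r$B, bayesc_prior(pi = 0.05), opts)
  f_ind <- blr_gibbs(crossprod(r$W$W), drop(crossprod(r$W$W, r$y)),
                     n = r$W$n, yty = sum(r$y^2),
                     prior = bayesc_prior(pi = 0.05), opts = opts,
                     ids = r$W$ids)
  expect_lt(max(abs(f_ss$pip - f_ind$pip)), 0.02)
})

test_that("genome-wide banded sampler agrees with the dense fit when the band covers m", {
  r <- make_region(n = 3000, m = 40, rho = 0.7, b = 0.12, seed = 31)
  opts <- mcmc_options(20000, 2000, seed = 8)
  fd <- fit_blr(r$ss, r$B, bayesc_prior(pi = 0.05), opts)
  Bb <- compute_ld(r$W, half_bandwidth = 39)
  fb <- fit_blr_genomewide(r$ss, Bb, bayesc_prior(pi = 0.05), opts)
  expect_lt(max(abs(fd$pip - fb$pip)), 0.05)
  # all-null summary stats stay quiet
  set.seed(32)
  ssn <- gwas_linear(r$W, rnorm(3000))
  fn <- fit_blr_genomewide(ssn, Bb, bayesc_prior(pi = 0.05),
                           mcmc_options(10000, 1000, seed = 9))
  expect_lt(max(fn$pip), 0.2)
  # doubling the chain leaves PIPs within Monte-Carlo bands
  fb2 <- fit_blr_genomewide(r$ss, Bb, bayesc_prior(pi = 0.05),
                            mcmc_options(40000, 2000, seed = 10))
  expect_lt(max(abs(fb$pip - fb2$pip)), 0.05)
  # narrow band with wide regions warns
  regions <- tibble::tibble(region_id = "r1", start_index = 1L, end_index = 40L)
  Bn <- compute_ld(r$W, half_bandwidth = 5)
  expect_warning(fit_blr_genomewide(r$ss, Bn, bayesc_prior(pi = 0.05),
                                    mcmc_options(2000, 200, seed = 1),
                                    regions = regions),
                 "band")
  expect_error(fit_blr_genomewide(r$ss, r$B, bayesc_prior()), "banded")
})

test_that("multiple independent runs are averaged and tracked", {
  r <- make_region(n = 1500, m = 20, b = 0.15, seed = 41)
  fit <- fit_blr(r$ss, r$B, bayesr_prior(), mcmc_options(4000, 500, nrun = 3, seed = 11))
  expect_length(fit$chains, 3)
  expect_equal(dim(fit$pip_runs), c(20L, 3L))
  expect_equal(fit$pip, rowMeans(fit$pip_runs))
  expect_gt(nrow(fit$geweke), 0)
})

test_that("ill-conditioned inputs produce actionable errors", {
  expect_error(blr_gibbs(diag(c(1, 0)), c(0, 0), n = 10, yty = 10,
                         prior = bayesc_prior(),
                         opts = mcmc_options(100, 10)),
               "jitter|ridge")
})

test_that("tidy and glance summarise a fit", {
  r <- make_region(n = 1500, m = 15, b = 0.15, seed = 51)
  fit <- fit_blr(r$ss, r$B, bayesr_prior(), mcmc_options(3000, 500, seed = 2))
  td <- tidy(fit)
  expect_named(td, c("id", "pip", "b_mean", paste0("class", 0:3)))
  expect_equal(nrow(td), 15)
  expect_true(all(td$pip >= 0 & td$pip <= 1))
  expect_equal(rowSums(as.matrix(td[, 4:7])), rep(1, 15), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$sigma_e2 > 0 && gl$sigma_b2 > 0)
  expect_type(gl$converged, "logical")
})

test_that("with estimate_pi the posterior concentrates near the true sparsity", {
  # one moderately informative instance; full coverage calibration is in the
  # acceptance suite
  g <- simulate_genotypes(8000, 200, maf_range = c(0.1, 0.4), ld_rho = 0.3, seed = 61)
  W <- scale_genotypes(g)
  sim <- simulate_ga1(W, m_causal = 10, h2 = 0.3, seed = 62)
  fit <- fit_blr(gwas_linear(W, sim$y), compute_ld(W),
                 bayesc_prior(estimate_pi = TRUE),
                 mcmc_options(8000, 1000, seed = 63))
  pi_chain <- 1 - dplyr::bind_rows(fit$chains)$pi1
  expect_gt(mean(pi_chain), 0.01)
  expect_lt(mean(pi_chain), 0.2)   # true value 0.05
})
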