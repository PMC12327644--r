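#' BayesC spike-and-slab prior
#'
#' SNP effects are zero with probability `1 - pi` and Gaussian
#' \eqn{N(0, \sigma_b^2)} with probability `pi`; `pi` is therefore the prior
#' probability of a NON-ZERO effect (the printed initial value 0.01 in the
#' usual fine-mapping configuration). The effect variance \eqn{\sigma_b^2}
#' carries a scaled inverse chi-square prior with degrees of freedom `nu_b` and
#' scale `s_b2`; by default the scale is set so the prior mean of
#' \eqn{\sigma_b^2} equals its initial value,
#' `s_b2 = sigma_b2_init * (nu_b - 2) / nu_b`.
#'
#' @param pi prior probability of a non-zero effect, in (0, 1].
#' @param estimate_pi update `pi` from the data (Beta conditional) each
#'   iteration, or keep it fixed.
#' @param nu_b prior degrees of freedom for \eqn{\sigma_b^2} (> 2).
#' @param s_b2 prior scale; `NULL` derives it from `sigma_b2_init` as above.
#' @param sigma_b2_init initial effect variance; `NULL` resolves at fit time to
#'   `h2_init / (m * pi)` (the value that would put heritability `h2_init` on
#'   `m * pi` scaled-genotype effects).
#' @param h2_init heritability guess used only for that default.
#' @return a `blr_prior` object.
#' @export
bayesc_prior <- function(pi = 0.01, estimate_pi = TRUE, nu_b = 4, s_b2 = NULL,
                         sigma_b2_init = NULL, h2_init = 0.1) {
  # pi = 0 (a degenerate all-null prior) is permitted: useful as a sampler
  # sanity check, and estimate_pi can move away from it
  assert_scalar_in(pi, 0, 1, "pi", open = c(FALSE, FALSE))
  if (nu_b <= 2) abort("`nu_b` must exceed 2")
  structure(list(type = "bayesc", gamma = c(0, 1), pi = c(1 - pi, pi),
                 estimate_pi = isTRUE(estimate_pi), alpha = c(1, 1),
                 nu_b = nu_b, s_b2 = s_b2, sigma_b2_init = sigma_b2_init,
                 h2_init = h2_init),
            class = "blr_prior")
}

#' BayesR finite-mixture prior
#'
#' SNP effects belong to one of `length(gamma)` classes: a null class
#' (`gamma[1] = 0`) plus Gaussian classes with variances
#' \eqn{\gamma_c \sigma_b^2}. `pi[1]` is the null-class probability. The
#' conventional initial values are `gamma = (0, 0.01, 0.1, 1)` and
#' `pi = (0.99, 0.06, 0.03, 0.01)`; the latter sums to 1.09 as printed in the
#' fine-mapping literature and is renormalized onto the simplex here (the raw
#' vector is kept as an attribute). Class probabilities are updated from a
#' Dirichlet(counts + alpha) conditional when `estimate_pi` is `TRUE`.
#'
#' @param gamma variance scaling factors; first element must be 0.
#' @param pi prior class probabilities (renormalized to sum 1).
#' @param estimate_pi update `pi` from the data each iteration.
#' @param alpha Dirichlet pseudo-counts.
#' @inheritParams bayesc_prior
#' @return a `blr_prior` object.
#' @export
bayesr_prior <- function(gamma = c(0, 0.01, 0.1, 1.0),
                         pi = c(0.99, 0.06, 0.03, 0.01),
                         estimate_pi = TRUE, alpha = rep(1, length(gamma)),
                         nu_b = 4, s_b2 = NULL, sigma_b2_init = NULL,
                         h2_init = 0.1) {
  if (gamma[1] != 0) abort("`gamma[1]` must be 0 (null class)")
  if (length(pi) != length(gamma) || length(alpha) != length(gamma))
    abort("`gamma`, `pi` and `alpha` must have equal length")
  if (any(pi <= 0)) abort("`pi` must be positive")
  if (nu_b <= 2) abort("`nu_b` must exceed 2")
  pin <- pi / sum(pi)
  structure(list(type = "bayesr", gamma = gamma, pi = pin,
                 estimate_pi = isTRUE(estimate_pi), alpha = alpha,
                 nu_b = nu_b, s_b2 = s_b2, sigma_b2_init = sigma_b2_init,
                 h2_init = h2_init, pi_raw = pi),
            class = "blr_prior")
}

#' @export
print.blr_prior <- function(x, ...) {
  cat(sprintf("<blr_prior> %s, %d classes, pi = (%s), %s\n", x$type,
              length(x$gamma), paste(signif(x$pi, 3), collapse = ", "),
              if (x$estimate_pi) "pi estimated" else "pi fixed"))
  invisible(x)
}

#' MCMC options for the Gibbs samplers
#'
#' @param n_iter total iterations per chain (> `n_burnin`).
#' @param n_burnin burn-in iterations discarded from all posterior summaries.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param nrun number of independent chains; posterior inclusion probabilities
#'   are averaged across runs (recommended for densely positioned SNPs).
#' @param seed master seed; each run gets its own derived stream.
#' @export
mcmc_options <- function(n_iter = 10000, n_burnin = 1000, thin = 1,
                         nrun = 1, seed = NULL) {
  n_iter <- assert_count(n_iter, "n_iter")
  n_burnin <- assert_count(n_burnin, "n_burnin", min = 0L)
  if (n_burnin >= n_iter) abort("`n_burnin` must be smaller than `n_iter`")
  structure(list(n_iter = n_iter, n_burnin = n_burnin,
                 thin = assert_count(thin, "thin"),
                 nrun = assert_count(nrun, "nrun"), seed = seed),
            class = "blr_mcmc_options")
}

# resolve data-dependent prior defaults once m is known
resolve_prior <- function(prior, m) {
  p_nonnull <- 1 - prior$pi[1]
  if (is.null(prior$sigma_b2_init)) {
    denom <- m * sum(prior$pi * prior$gamma)
    prior$sigma_b2_init <- prior$h2_init / max(denom, 1e-12)
  }
  if (is.null(prior$s_b2))
    prior$s_b2 <- prior$sigma_b2_init * (prior$nu_b - 2) / prior$nu_b
  prior
}

#' Low-level Gibbs sampler on sufficient statistics
#'
#' Runs the single-site Gibbs sampler with residual updating on a given
#' \eqn{X'X} / \eqn{X'y} system. This is the engine behind [fit_blr()] and
#' [fit_blr_genomewide()]; it is exported so that individual-level fits
#' (`XtX = W'W`, `Xty = W'y`, `yty = y'y`) use exactly the same code path as
#' summary-statistic fits.
#'
#' @param XtX dense m x m cross-product matrix, or a `blr_suffstats` object
#'   (in which case `Xty`, `n`, `yty` are taken from it).
#' @param Xty length-m right-hand side.
#' @param n sample size (used in the residual-variance conditional).
#' @param yty total sum of squares of the phenotype (`n` for a variance-1
#'   phenotype).
#' @param prior a `blr_prior`.
#' @param opts a `blr_mcmc_options`.
#' @param ids optional variant ids.
#' @param update_sigma_b2,update_sigma_e2 set `FALSE` to hold a variance fixed
#'   at its initial value (used by the enumeration-oracle comparisons).
#' @param sigma_e2_init initial residual variance.
#' @return a `blr_fit` object; see [tidy.blr_fit()] and [glance.blr_fit()].
#' @export
blr_gibbs <- function(XtX, Xty = NULL, n = NULL, yty = NULL, prior, opts = mcmc_options(),
                      ids = NULL, update_sigma_b2 = TRUE, update_sigma_e2 = TRUE,
                      sigma_e2_init = 1) {
  banded <- FALSE
  hb <- 0L
  if (inherits(XtX, "blr_suffstats")) {
    sf <- XtX
    Xty <- sf$Xty
    n <- sf$n_eff
    yty <- sf$yty
    ids <- ids %||% sf$ids
    banded <- sf$layout == "banded"
    hb <- if (banded) sf$half_bandwidth else 0L
    XtX <- sf$XtX
  }
  stopifnot(is.numeric(Xty), length(n) == 1L, length(yty) == 1L)
  m <- length(Xty)
  ids <- ids %||% sprintf("v%d", seq_len(m))
  prior <- resolve_prior(prior, m)
  C <- length(prior$gamma)
  nu_e <- 4
  s_e2 <- sigma_e2_init * (nu_e - 2) / nu_e

  seeds <- seed_streams(opts$seed, sprintf("run%d", seq_len(opts$nrun)))
  runs <- vector("list", opts$nrun)
  for (r in seq_len(opts$nrun)) {
    runs[[r]] <- with_seed(if (is.null(seeds)) NULL else seeds[r],
      blr_gibbs_cpp(if (banded) matrix(0, 0, 0) else XtX,
                    if (banded) XtX else matrix(0, 0, 0),
                    banded, as.integer(hb),
                    Xty, n, yty,
                    prior$gamma, prior$pi, prior$estimate_pi, prior$alpha,
                    prior$nu_b, prior$s_b2, nu_e, s_e2,
                    update_sigma_b2, update_sigma_e2,
                    prior$sigma_b2_init, sigma_e2_init,
                    opts$n_iter, opts$n_burnin, opts$thin))
  }
  pip_runs <- matrix(vapply(runs, function(x) x$pip, numeric(m)), nrow = m)
  b_runs <- matrix(vapply(runs, function(x) x$b_mean, numeric(m)), nrow = m)
  chains <- lapply(runs, function(x) {
    ch <- x$chains
    colnames(ch) <- c("sigma_b2", "sigma_e2", "sigma_g2", "k",
                      sprintf("pi%d", seq_len(C)))
    as_tibble(ch)
  })
  gw <- geweke_fit_chains(chains)
  cls <- Reduce(`+`, lapply(runs, function(x) x$cls_prob)) / opts$nrun
  colnames(cls) <- sprintf("class%d", seq_len(C) - 1L)
  structure(
    list(pip = rowMeans(pip_runs), b_mean = rowMeans(b_runs),
         class_prob = cls, chains = chains,
         pip_runs = pip_runs, ids = ids, prior = prior, opts = opts,
         n = n, m = m, geweke = gw,
         converged = nrow(gw) == 0 ||
           (all(gw$assessable) && all(abs(gw$z) <= 3)),
         n_sse_clamped = sum(vapply(runs, function(x) x$n_sse_clamped, 0L))),
    class = "blr_fit")
}

# Geweke z for the monitored hyperparameters of every run. Chains that are
# constant by design (a fixed hyperparameter) carry no convergence information
# and are skipped rather than flagged.
geweke_fit_chains <- function(chains) {
  params <- c("sigma_b2", "sigma_e2", "sigma_g2", "pi1")
  purrr::map_dfr(seq_along(chains), function(r) {
    keep <- params[vapply(params, function(p) sd(chains[[r]][[p]]) > 0, logical(1))]
    purrr::map_dfr(keep, function(p) {
      g <- geweke_z(chains[[r]][[p]])
      tibble(run = r, param = p, z = g$z, assessable = g$assessable)
    })
  })
}

#' Fit a Bayesian linear regression fine-mapping model to summary statistics
#'
#' Reconstructs \eqn{X'X} and \eqn{X'y} from the marginal effects and the LD
#' matrix, then samples the joint effect posterior under the chosen prior.
#' The per-variant posterior inclusion probability (PIP) is the fraction of
#' kept iterations in which the variant carries a non-zero effect, averaged
#' over `opts$nrun` independent chains.
#'
#' @param ss a `blr_sumstats` tibble for one fine-mapping region.
#' @param B a dense `ld_matrix` aligned with `ss`.
#' @param prior a `blr_prior` ([bayesc_prior()] or [bayesr_prior()]).
#' @param opts a [mcmc_options()].
#' @param scaled passed to [reconstruct_suffstats()].
#' @param ridge diagonal jitter added to X'X expressed as a fraction of the
#'   mean diagonal (stabilises nearly singular in-sample LD); 0 disables.
#' @return a `blr_fit`.
#' @export
fit_blr <- function(ss, B, prior, opts = mcmc_options(), scaled = TRUE, ridge = 0) {
  sf <- reconstruct_suffstats(ss, B, scaled = scaled)
  if (ridge > 0) {
    if (sf$layout == "dense") {
      diag(sf$XtX) <- diag(sf$XtX) * (1 + ridge)
    } else {
      sf$XtX[1, ] <- sf$XtX[1, ] * (1 + ridge)
    }
  }
  blr_gibbs(sf, prior = prior, opts = opts)
}

#' Genome-wide fit with banded LD
#'
#' Same sampler as [fit_blr()] applied across the whole panel with a banded LD
#' matrix: a variant's residual update touches only neighbours within the
#' band, so the cost per sweep is O(m * bandwidth). PIPs can afterwards be
#' sliced per fine-mapping region for credible-set construction.
#'
#' @param ss genome-wide `blr_sumstats`.
#' @param B_banded a banded `ld_matrix` aligned with `ss`.
#' @param prior,opts,scaled as in [fit_blr()].
#' @param regions optional region tibble (from [regions_from_causals()] /
#'   [regions_from_leads()]); a warning is issued if any region is wider than
#'   the band.
#' @return a `blr_fit`.
#' @export
fit_blr_genomewide <- function(ss, B_banded, prior, opts = mcmc_options(),
                               scaled = TRUE, regions = NULL) {
  stopifnot(inherits(B_banded, "ld_matrix"))
  if (B_banded$layout != "banded")
    abort("`B_banded` must use the banded layout (see compute_ld(half_bandwidth=))")
  if (!is.null(regions)) {
    wide <- regions$end_index - regions$start_index
    if (any(wide > B_banded$half_bandwidth))
      warn("some regions are wider than the LD half bandwidth; cross-region shrinkage will be truncated")
  }
  sf <- reconstruct_suffstats(ss, B_banded, scaled = scaled)
  blr_gibbs(sf, prior = prior, opts = opts)
}

#' Exact posterior inclusion probabilities by model enumeration
#'
#' Test oracle for the Gibbs samplers: enumerates all \eqn{2^m} inclusion
#' patterns of a (small) spike-and-slab system with FIXED hyperparameters,
#' computes each model's Gaussian marginal likelihood from \eqn{X'X} and
#' \eqn{X'y}, weights it by \eqn{\pi^k (1-\pi)^{m-k}}, and returns exact
#' per-variant inclusion probabilities. Refuses m > 12.
#'
#' @param ss,B summary statistics and dense LD (as in [fit_blr()]), or pass
#'   `XtX`, `Xty` directly.
#' @param sigma_b2,sigma_e2 fixed effect and residual variances.
#' @param pi fixed non-zero prior probability.
#' @param XtX,Xty optional direct sufficient statistics (bypass `ss`/`B`).
#' @param scaled passed to [reconstruct_suffstats()].
#' @return numeric vector of exact PIPs.
#' @export
exact_posterior_oracle <- function(ss = NULL, B = NULL, sigma_b2, sigma_e2, pi,
                                   XtX = NULL, Xty = NULL, scaled = TRUE) {
  if (is.null(XtX)) {
    sf <- reconstruct_suffstats(ss, B, scaled = scaled)
    if (sf$layout != "dense") abort("oracle requires dense LD")
    XtX <- sf$XtX
    Xty <- sf$Xty
  }
  m <- length(Xty)
  if (m > 12) abort("enumeration oracle refuses m > 12")
  assert_scalar_in(pi, 0, 1, "pi")
  logodds <- log(pi) - log1p(-pi)
  logw <- numeric(2^m)
  masks <- vector("list", 2^m)
  for (s in 0:(2^m - 1)) {
    inc <- which(bitwAnd(s, bitwShiftL(1L, 0:(m - 1))) != 0L)
    k <- length(inc)
    lw <- k * logodds
    if (k > 0) {
      M <- XtX[inc, inc, drop = FALSE] / sigma_e2 + diag(1 / sigma_b2, k)
      u <- Xty[inc] / sigma_e2
      ch <- chol(M)
      v <- backsolve(ch, u, transpose = TRUE)
      lw <- lw - k * log(sigma_b2) / 2 - sum(log(diag(ch))) + sum(v^2) / 2
    }
    logw[s + 1] <- lw
    masks[[s + 1]] <- inc
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  pip <- numeric(m)
  for (s in seq_along(w)) pip[masks[[s]]] <- pip[masks[[s]]] + w[s]
  pip
}

#' @export
print.blr_fit <- function(x, ...) {
  cat(sprintf("<blr_fit> %s prior, %d variants, %d x %d iterations (%d burn-in), %s\n",
              x$prior$type, x$m, x$opts$nrun, x$opts$n_iter, x$opts$n_burnin,
              if (x$converged) "converged" else "NOT converged (|Geweke z| > 3)"))
  cat(sprintf("  max PIP %.3f at %s\n", max(x$pip), x$ids[which.max(x$pip)]))
  invisible(x)
}

#' Tidy per-variant posterior summaries
#'
#' @param x a `blr_fit`.
#' @param ... unused.
#' @return tibble with id, pip, b_mean and posterior class probabilities.
#' @method tidy blr_fit
#' @export
tidy.blr_fit <- function(x, ...) {
  out <- tibble(id = x$ids, pip = x$pip, b_mean = x$b_mean)
  dplyr::bind_cols(out, as_tibble(x$class_prob))
}

#' One-row model-level summary
#'
#' Posterior means of the hyperparameters (pooled across runs and kept
#' iterations), the estimated non-null probability, and convergence.
#'
#' @param x a `blr_fit`.
#' @param ... unused.
#' @method glance blr_fit
#' @export
glance.blr_fit <- function(x, ...) {
  ch <- dplyr::bind_rows(x$chains)
  tibble(sigma_b2 = mean(ch$sigma_b2), sigma_e2 = mean(ch$sigma_e2),
         sigma_g2 = mean(ch$sigma_g2), pi_nonnull = mean(1 - ch$pi1),
         k_mean = mean(ch$k), n_iter = x$opts$n_iter,
         n_burnin = x$opts$n_burnin, nrun = x$opts$nrun,
         max_abs_geweke_z = if (nrow(x$geweke)) max(abs(x$geweke$z), na.rm = TRUE) else NA_real_,
         converged = x$converged)
}
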