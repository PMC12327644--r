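#' Simulate a quantitative phenotype under a single-class polygenic
#' architecture (GA1)
#'
#' `m_causal` causal variants are sampled without replacement; their effects on
#' the centered-and-scaled genotype scale are drawn from
#' \eqn{N(0, \sigma_g^2 / m_C)} with \eqn{\sigma_g^2 = h^2}, and the residual
#' from \eqn{N(0, \sigma_g^2 (1/h^2 - 1))}, so the expected phenotypic variance
#' is 1 and the SNP heritability equals `h2`.
#'
#' @param geno a `scaled_design` or `geno_matrix` (causal columns are scaled
#'   in-sample on demand).
#' @param m_causal number of causal variants.
#' @param h2 target SNP heritability, in (0, 1).
#' @param seed integer seed.
#' @return an object of class `sim_phenotype`: list with `y`, `h2`,
#'   `sigma_g2`, `sigma_e2`, `g` (genetic values), and `causal`, a tibble
#'   (index, id, effect, class).
#' @export
simulate_ga1 <- function(geno, m_causal, h2, seed = NULL) {
  assert_scalar_in(h2, 0, 1, "h2")
  m <- geno_m(geno)
  m_causal <- assert_count(m_causal, "m_causal")
  if (m_causal > m) abort("`m_causal` cannot exceed the number of variants")
  with_seed(seed, {
    idx <- sort(sample.int(m, m_causal))
    b <- rnorm(m_causal, 0, sqrt(h2 / m_causal))
    new_sim_phenotype(geno, idx, b, rep("ga1", m_causal), sigma_g2 = h2,
                      sigma_e2 = h2 * (1 / h2 - 1), h2 = h2)
  })
}

#' Simulate a quantitative phenotype under a three-class mixture architecture
#' (GA2)
#'
#' Causal variants fall into small / moderate / large effect classes in
#' proportions 93% / 5% / 2% (largest-remainder allocation of the counts, then
#' random assignment). Per-variant effect variances are
#' \eqn{0.6 \sigma_g^2 / m_{C1}}, \eqn{0.2 \sigma_g^2 / m_{C2}} and
#' \eqn{0.2 \sigma_g^2 / m_{C3}}, so the classes contribute 60% / 20% / 20% of
#' the genetic variance in expectation.
#'
#' @inheritParams simulate_ga1
#' @export
simulate_ga2 <- function(geno, m_causal, h2, seed = NULL) {
  assert_scalar_in(h2, 0, 1, "h2")
  m <- geno_m(geno)
  m_causal <- assert_count(m_causal, "m_causal")
  if (m_causal > m) abort("`m_causal` cannot exceed the number of variants")
  share <- c(small = 0.6, moderate = 0.2, large = 0.2)
  prop <- c(small = 0.93, moderate = 0.05, large = 0.02)
  counts <- largest_remainder(prop * m_causal)
  if (any(counts == 0))
    abort("each GA2 effect-size class needs at least one causal variant; increase `m_causal`")
  with_seed(seed, {
    idx <- sort(sample.int(m, m_causal))
    cls <- sample(rep(names(prop), counts))
    v <- (share[cls] * h2) / counts[cls]
    b <- rnorm(m_causal, 0, sqrt(v))
    new_sim_phenotype(geno, idx, b, cls, sigma_g2 = h2,
                      sigma_e2 = h2 * (1 / h2 - 1), h2 = h2)
  })
}

# integer allocation hitting the target proportions exactly
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- sum(round(sum(x))) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  setNames(as.integer(fl), names(x))
}

#' Simulate a region phenotype with two causal variants
#'
#' Two distinct variants drawn uniformly from the region carry fixed effects on
#' the scaled-genotype scale -- large (L) 0.05 and/or small (S) 0.01 -- and the
#' residual variance is fixed at 1.0 (the phenotype is not rescaled), giving
#' per-variant heritabilities of approximately 0.0025 (L) and 0.001 (S).
#'
#' @param geno region genotypes (`scaled_design` or `geno_matrix`, >= 2
#'   variants).
#' @param config `"LL"`, `"LS"` or `"SS"` effect-size configuration.
#' @param seed integer seed.
#' @return a `sim_phenotype`.
#' @export
simulate_two_causal <- function(geno, config = c("LL", "LS", "SS"), seed = NULL) {
  if (!is.character(config) || length(config) != 1L || !config %in% c("LL", "LS", "SS"))
    abort("`config` must be one of \"LL\", \"LS\", \"SS\"")
  m <- geno_m(geno)
  if (m < 2) abort("region must contain at least 2 variants")
  eff <- c(L = 0.05, S = 0.01)
  cls <- strsplit(config, "")[[1]]
  with_seed(seed, {
    idx <- sort(sample.int(m, 2))
    b <- unname(eff[cls])
    new_sim_phenotype(geno, idx, b, cls, sigma_g2 = sum(b^2), sigma_e2 = 1,
                      h2 = sum(b^2) / (sum(b^2) + 1))
  })
}

new_sim_phenotype <- function(geno, idx, b, cls, sigma_g2, sigma_e2, h2) {
  g <- geno_genetic_value(geno, idx, b)
  y <- g + rnorm(geno_n(geno), 0, sqrt(sigma_e2))
  structure(
    list(y = y, g = g, h2 = h2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         causal = tibble(index = idx, id = geno_ids(geno)[idx],
                         effect = b, class = unname(cls)),
         binary = NULL, prevalence = NULL, n = geno_n(geno)),
    class = "sim_phenotype")
}

#' @export
print.sim_phenotype <- function(x, ...) {
  cat(sprintf("<sim_phenotype> n=%d, %d causal, h2=%.3f, var(y)=%.3f%s\n",
              x$n, nrow(x$causal), x$h2, var(x$y),
              if (!is.null(x$binary)) sprintf(", binary (PV=%.2f)", x$prevalence) else ""))
  invisible(x)
}

#' Dichotomize a quantitative phenotype into cases and controls
#'
#' The `round(n * prevalence)` individuals with the largest phenotype values
#' become cases (liability-threshold construction); ties are broken by sample
#' index so the case count is always exact.
#'
#' @param y numeric phenotype vector, or a `sim_phenotype` (in which case the
#'   labels are attached to it and the object returned).
#' @param prevalence case fraction PV in (0, 1); `n * prevalence` must be >= 1.
#' @return integer 0/1 labels, or the updated `sim_phenotype`.
#' @export
dichotomize <- function(y, prevalence) {
  UseMethod("dichotomize")
}

#' @export
dichotomize.default <- function(y, prevalence) {
  assert_scalar_in(prevalence, 0, 1, "prevalence")
  n <- length(y)
  k <- round(n * prevalence)
  if (k < 1) abort("`prevalence` too small: n * prevalence must be >= 1")
  lab <- integer(n)
  lab[order(-y, seq_len(n))[seq_len(k)]] <- 1L
  lab
}

#' @export
dichotomize.sim_phenotype <- function(y, prevalence) {
  y$binary <- dichotomize(y$y, prevalence)
  y$prevalence <- prevalence
  y
}

#' Write phenotype and causal-truth tables
#'
#' @param sim a `sim_phenotype`.
#' @param path output TSV path (phenotype); the truth table goes to
#'   `<path>.truth`.
#' @export
write_phenotype <- function(sim, path) {
  stopifnot(inherits(sim, "sim_phenotype"))
  ph <- tibble(sample_id = seq_len(sim$n), y = sim$y)
  if (!is.null(sim$binary)) ph$case <- sim$binary
  readr::write_tsv(ph, path)
  readr::write_tsv(sim$causal, paste0(path, ".truth"))
  invisible(path)
}
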