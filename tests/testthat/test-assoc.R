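test_that("linear GWAS is calibrated under the null and unbiased under signal", {
  g <- simulate_genotypes(400, 40, maf_range = c(0.1, 0.4), ld_rho = 0, seed = 30)
  W <- scale_genotypes(g)
  # type-I error at alpha = 0.05 across many null phenotypes
  set.seed(31)
  pvals <- replicate(250, gwas_linear(W, rnorm(400))$pvalue)
  expect_true(mean(pvals < 0.05) > 0.035 && mean(pvals < 0.05) < 0.065)
  # z-scores standard normal (Kolmogorov-Smirnov on pooled null scans)
  set.seed(32)
  z <- as.numeric(replicate(250, { s <- gwas_linear(W, rnorm(400)); s$beta / s$se }))
  expect_gt(suppressWarnings(ks.test(z, "pnorm")$p.value), 0.01)
})

test_that("marginal effects recover the true effect without LD and se ~ 1/sqrt(n)", {
  n <- 2000
  g <- simulate_genotypes(n, 10, maf_range = c(0.2, 0.4), ld_rho = 0, seed = 33)
  W <- scale_genotypes(g)
  bhat <- vapply(1:50, function(s) {
    set.seed(400 + s)
    y <- 0.1 * W$W[, 1] + rnorm(n)
    gwas_linear(W, y)$beta[1]
  }, numeric(1))
  expect_equal(mean(bhat), 0.1, tolerance = 0.015)
  set.seed(34)
  ssn <- gwas_linear(W, rnorm(n))
  expect_equal(mean(ssn$se), 1 / sqrt(n), tolerance = 0.05)
  expect_error(gwas_linear(W, rep(1, 3)), "length")
})

test_that("geno-matrix and scaled-design GWAS paths agree exactly", {
  r <- make_region(n = 1500, m = 30, seed = 40)
  ss2 <- gwas_linear(r$g, r$y)
  expect_equal(r$ss$beta, ss2$beta, tolerance = 1e-12)
  expect_equal(r$ss$se, ss2$se, tolerance = 1e-12)
  expect_equal(r$ss$pvalue, ss2$pvalue, tolerance = 1e-10)
})

test_that("logistic GWAS matches glm, respects symmetry, and flags separation", {
  n <- 1500
  g <- simulate_genotypes(n, 25, maf_range = c(0.1, 0.4), ld_rho = 0.3, seed = 50)
  W <- scale_genotypes(g)
  set.seed(51)
  liab <- 0.4 * W$W[, 5] + rnorm(n)
  lab <- dichotomize(liab, 0.3)
  ss <- gwas_logistic(g, lab)
  expect_true(all(ss$converged))
  # independent oracle: stats::glm on a handful of variants
  for (j in c(1, 5, 17)) {
    fit <- glm(lab ~ W$W[, j], family = binomial())
    expect_equal(ss$beta[j], unname(coef(fit)[2]), tolerance = 1e-5)
    expect_equal(ss$se[j], unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-5)
  }
  # flipping case/control labels negates the slope
  ssf <- gwas_logistic(g, 1L - lab)
  expect_equal(ssf$beta, -ss$beta, tolerance = 1e-6)
  # permuting labels destroys the association on the causal variant
  set.seed(52)
  ssp <- gwas_logistic(g, sample(lab))
  expect_lt(abs(ssp$beta[5] / ssp$se[5]), abs(ss$beta[5] / ss$se[5]))
  # null variants keep |z| modest
  expect_lt(max(abs((ss$beta / ss$se)[-(4:6)])), 6)
  expect_error(gwas_logistic(g, rep(1L, n)), "both classes")
})

test_that("logistic null z-scores are approximately standard normal", {
  n <- 600
  g <- simulate_genotypes(n, 30, maf_range = c(0.15, 0.4), ld_rho = 0, seed = 55)
  set.seed(56)
  z <- as.numeric(replicate(60, {
    lab <- rbinom(n, 1, 0.3)
    ss <- gwas_logistic(g, lab)
    (ss$beta / ss$se)[ss$converged]
  }))
  expect_gt(mean(abs(z) < 4), 0.9998 - 0.002)  # essentially no |z| >= 4 under the null
  expect_equal(mean(z), 0, tolerance = 0.05)
})

test_that("standardizing summary statistics preserves z and fixes the scale", {
  r <- make_region(n = 2000, m = 20, b = 0.15, seed = 45)
  # near-identity for a linear GWAS of a ~variance-1 phenotype
  std <- standardize_sumstats(r$ss)
  expect_equal(std$beta / std$se, r$ss$beta / r$ss$se, tolerance = 1e-12)
  expect_equal(std$beta, r$ss$beta, tolerance = 0.05)
  expect_equal(std$se, rep(1 / sqrt(2000), 20), tolerance = 0.05)
  # logistic effects land on the same scale as a linear scan of the labels
  set.seed(46)
  lab <- dichotomize(0.5 * r$W$W[, 3] + rnorm(2000), 0.3)
  stdl <- standardize_sumstats(gwas_logistic(r$g, lab))
  lin <- gwas_linear(r$W, drop(scale(lab)))
  # logistic and linear z agree closely away from strong effects; the scales
  # coincide overall
  weak <- abs(lin$beta / lin$se) < 5
  expect_lt(max(abs(stdl$beta - lin$beta)[weak]), 0.02)
  expect_gt(cor(stdl$beta, lin$beta), 0.99)
  # non-finite z (unconverged fits) enter as null variants
  broken <- r$ss
  broken$se[4] <- NA_real_
  expect_equal(standardize_sumstats(broken)$beta[4], 0)
})

test_that("LD matrices have the documented structure", {
  r <- make_region(n = 1200, m = 20, rho = 0.6, seed = 60)
  B <- r$B
  expect_equal(unname(diag(B$r)), rep(1, 20), tolerance = 1e-12)
  expect_equal(B$r, t(B$r), tolerance = 1e-12)
  expect_true(all(abs(B$r) <= 1 + 1e-12))
  # duplicated column gives off-diagonal 1
  g <- r$g
  g$counts[, 2] <- g$counts[, 1]
  Bd <- compute_ld(g)
  expect_equal(Bd$r[1, 2], 1, tolerance = 1e-12)
  # independent columns at n = 10000: off-diagonals near zero
  gi <- simulate_genotypes(10000, 12, maf_range = c(0.2, 0.4), ld_rho = 0, seed = 61)
  Bi <- compute_ld(gi)
  expect_lt(max(abs(Bi$r[upper.tri(Bi$r)])), 0.05)
  # banded equals dense within the band, zero outside
  Bb <- compute_ld(g, half_bandwidth = 2)
  Bbm <- as.matrix(Bb)
  for (k in 0:2) for (j in seq_len(20 - k))
    expect_equal(Bbm[j, j + k], Bd$r[j, j + k], tolerance = 1e-12)
  expect_equal(Bbm[1, 4], 0)
  # geno and scaled-design LD agree
  expect_equal(compute_ld(r$W)$r, compute_ld(r$g)$r, tolerance = 1e-12)
  # subsampled LD is an estimate from fewer individuals
  Bs <- compute_ld(r$g, subsample_n = 600, seed = 1)
  expect_equal(unname(diag(Bs$r)), rep(1, 20), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(Bs$r, Bd$r)))
})

test_that("Eq-6 style reconstruction reproduces direct cross-products exactly", {
  for (m in c(50, 200, 500)) {
    r <- make_region(n = 1000, m = m, rho = 0.8, seed = 70 + m)
    sf <- reconstruct_suffstats(r$ss, r$B, scaled = TRUE)
    XtX <- crossprod(r$W$W)
    Xty <- drop(crossprod(r$W$W, r$y))
    expect_lt(norm(sf$XtX - XtX, "F") / norm(XtX, "F"), 1e-6)
    expect_lt(sqrt(sum((sf$Xty - Xty)^2) / sum(Xty^2)), 1e-6)
  }
})

test_that("reconstruction identities for special LD structures hold", {
  ss <- make_sumstats(beta = c(0.1, -0.05, 0.02), se = c(0.01, 0.01, 0.01),
                      n = c(100, 200, 400))
  B <- ld_from_matrix(diag(3), ids = ss$id)
  sf <- reconstruct_suffstats(ss, B, scaled = TRUE)
  expect_equal(sf$XtX, diag(c(100, 200, 400)), ignore_attr = TRUE)
  expect_equal(sf$Xty, c(100, 200, 400) * ss$beta)
  # constant n: X'X = n * B
  R <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  ssc <- make_sumstats(beta = c(0.1, 0, 0), se = rep(0.01, 3), n = 500)
  sfc <- reconstruct_suffstats(ssc, ld_from_matrix(R, ids = ssc$id))
  expect_equal(sfc$XtX, 500 * R, ignore_attr = TRUE)
  # unscaled path uses D = 1/(se^2 + beta^2/n)
  sfu <- reconstruct_suffstats(ssc, ld_from_matrix(R, ids = ssc$id), scaled = FALSE)
  expect_equal(sfu$D, 1 / (ssc$se^2 + ssc$beta^2 / ssc$n))
  # misaligned ids error names the first mismatch
  Bbad <- ld_from_matrix(R, ids = c("v1", "vX", "v3"))
  expect_error(reconstruct_suffstats(ssc, Bbad), "vX")
})

test_that("summary statistics and LD survive a TSV round trip", {
  r <- make_region(n = 500, m = 15, seed = 80)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(r$ss, p1)
  ss2 <- read_sumstats(p1)
  expect_equal(ss2$beta, r$ss$beta, tolerance = 1e-9)
  expect_s3_class(ss2, "blr_sumstats")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_ld(r$B, p2)
  B2 <- read_ld(p2)
  expect_equal(B2$r, r$B$r, tolerance = 1e-9, ignore_attr = TRUE)
  Bb <- compute_ld(r$W, half_bandwidth = 3)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_ld(Bb, p3)
  B3 <- read_ld(p3, layout = "banded", half_bandwidth = 3)
  expect_equal(B3$r, Bb$r, tolerance = 1e-9)
})
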