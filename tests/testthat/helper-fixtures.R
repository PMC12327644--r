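# shared fixture builders; everything is generated in code at test time

# small region: genotypes, scaled design, phenotype with one causal variant,
# summary statistics and in-sample LD
make_region <- function(n = 3000, m = 50, rho = 0.7, b = 0.1, causal = 1,
                        seed = 1, maf = c(0.05, 0.45)) {
  g <- simulate_genotypes(n, m, maf_range = maf, ld_rho = rho, seed = seed)
  W <- scale_genotypes(g)
  bvec <- rep(0, m)
  bvec[causal] <- b
  set.seed(seed + 1000)
  y <- drop(W$W %*% bvec) + rnorm(n)
  ss <- gwas_linear(W, y)
  list(g = g, W = W, y = y, ss = ss, B = compute_ld(W), causal = causal,
       b = bvec)
}

# hand-built summary statistics tibble (already "aligned" with a given LD)
make_sumstats <- function(beta, se, n, ids = sprintf("v%d", seq_along(beta)),
                          pos = seq_along(beta)) {
  out <- tibble::tibble(id = ids, chrom = "1", pos = pos, a1 = "A", a0 = "G",
                        freq = 0.3, beta = beta, se = se, n = n,
                        pvalue = 2 * stats::pnorm(-abs(beta / se)))
  class(out) <- c("blr_sumstats", class(out))
  out
}

ld_from_matrix <- function(R, ids = sprintf("v%d", seq_len(nrow(R)))) {
  blrfine:::new_ld_matrix(unname(R), ids, "dense", NULL)
}
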