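#' Simulate LD-structured genotype dosages
#'
#' Draws each individual as two haplotypes from a first-order autocorrelated
#' (AR(1)) standard-normal latent process thresholded at per-variant allele
#' frequencies, giving dosages in \{0, 1, 2\} with Hardy-Weinberg marginals and
#' a banded, tunable LD structure: adjacent-variant genotype correlation
#' increases monotonically with `ld_rho`. This is a stand-in for real cohort
#' genotypes, built so that banded genome-wide LD and LD-aware credible sets
#' can be exercised; it makes no claim about any particular population's LD.
#'
#' @param n number of individuals (>= 2).
#' @param m number of variants (>= 1).
#' @param maf_range length-2 numeric, lower/upper bound of the effect-allele
#'   frequency spectrum; frequencies are drawn uniformly inside it. The default
#'   floor of 0.01 mirrors the usual GWAS QC exclusion of rarer variants.
#' @param ld_rho AR(1) correlation of the latent haplotype process, in `[0, 1)`.
#'   `0` gives independent variants.
#' @param chrom chromosome label for all variants.
#' @param pos_spacing basepair spacing between consecutive variants
#'   (1-based positions `1, 1 + s, 1 + 2 s, ...`).
#' @param seed integer seed; the call is reproducible given the seed.
#' @return an object of class `geno_matrix`: a list with integer matrix
#'   `counts` (n x m), `freqs` (the requested population frequencies),
#'   `positions`, `chrom`, `ids`, and effect/other allele codes `a1`/`a0`.
#' @examples
#' g <- simulate_genotypes(200, 50, maf_range = c(0.05, 0.45), ld_rho = 0.8, seed = 1)
#' dim(g$counts)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.01, 0.49), ld_rho = 0.9,
                               chrom = "1", pos_spacing = 1000L, seed = NULL) {
  n <- assert_count(n, "n", min = 2L)
  m <- assert_count(m, "m", min = 1L)
  if (length(maf_range) != 2L || !all(is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[1] > maf_range[2] || maf_range[2] >= 0.5)
    abort("`maf_range` must satisfy 0 < lo <= hi < 0.5")
  assert_scalar_in(ld_rho, 0, 1, "ld_rho", open = c(FALSE, TRUE))
  with_seed(seed, {
    freqs <- stats::runif(m, maf_range[1], maf_range[2])
    counts <- simulate_genotypes_cpp(n, m, freqs, ld_rho)
  })
  ids <- sprintf("snp%d", seq_len(m))
  colnames(counts) <- ids
  structure(
    list(counts = counts, freqs = freqs,
         positions = 1L + (seq_len(m) - 1L) * as.integer(pos_spacing),
         chrom = rep(as.character(chrom), m), ids = ids,
         a1 = rep("A", m), a0 = rep("G", m), n = n, m = m),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants, chrom %s, MAF %.3f-%.3f\n",
              x$n, x$m, x$chrom[1], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Center and scale genotype dosages
#'
#' Builds the scaled design matrix `W` with columns
#' \eqn{w_i = (x_i - 2 p_i) / \sqrt{2 p_i (1 - p_i)}}. When
#' `use_sample_freq = TRUE` (the default, the in-sample convention used by the
#' whole summary-statistics pipeline) the column is centered at its sample mean
#' and scaled by its realized standard deviation (denominator n), which equals
#' \eqn{\sqrt{2 p (1 - p)}} under Hardy-Weinberg equilibrium and makes every
#' column exactly mean 0, variance 1 in sample -- the condition under which the
#' summary-statistic reconstruction of X'X and X'y is algebraically exact.
#' With `use_sample_freq = FALSE` the literal formula is applied with the
#' supplied population frequencies.
#'
#' @param G a `geno_matrix`.
#' @param use_sample_freq re-estimate frequencies (and dosage variance) from
#'   `G` instead of using `G$freqs`.
#' @return an object of class `scaled_design` with the dense `W` matrix.
#' @export
scale_genotypes <- function(G, use_sample_freq = TRUE) {
  stopifnot(inherits(G, "geno_matrix"))
  st <- geno_col_stats_cpp(G$counts)
  if (use_sample_freq) {
    center <- st$mean
    scale <- st$sd
    freqs <- st$mean / 2
  } else {
    center <- 2 * G$freqs
    scale <- sqrt(2 * G$freqs * (1 - G$freqs))
    freqs <- G$freqs
  }
  mono <- which(st$sd <= 0 | freqs <= 0 | freqs >= 1)
  if (length(mono))
    abort(sprintf("monomorphic variant(s): %s",
                  paste(G$ids[head(mono, 5)], collapse = ", ")))
  W <- (matrix(as.double(G$counts), nrow = G$n) -
          rep(center, each = G$n)) / rep(scale, each = G$n)
  colnames(W) <- G$ids
  structure(list(W = W, ids = G$ids, center = center, scale = scale,
                 freqs = freqs, positions = G$positions, chrom = G$chrom,
                 n = G$n, m = G$m),
            class = "scaled_design")
}

#' @export
print.scaled_design <- function(x, ...) {
  cat(sprintf("<scaled_design> %d x %d (centered, scaled in-sample)\n", x$n, x$m))
  invisible(x)
}

# scaled columns for a subset of variants, without materialising the full W;
# works on either container. Used by the phenotype simulators and PGS.
geno_scaled_cols <- function(geno, idx) {
  if (inherits(geno, "scaled_design")) return(geno$W[, idx, drop = FALSE])
  stopifnot(inherits(geno, "geno_matrix"))
  x <- matrix(as.double(geno$counts[, idx, drop = FALSE]), nrow = geno$n)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(x^2) - mu^2)
  if (any(sdv <= 0)) abort("monomorphic variant among requested columns")
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}

# weighted sum of in-sample scaled columns (a genetic value / polygenic
# score), streamed in C++ for the integer container so no dense double
# submatrix is allocated
geno_genetic_value <- function(geno, idx, effects) {
  if (inherits(geno, "scaled_design"))
    return(drop(geno$W[, idx, drop = FALSE] %*% effects))
  stopifnot(inherits(geno, "geno_matrix"))
  st <- geno_col_stats_idx_cpp(geno$counts, as.integer(idx) - 1L)
  if (any(st$sd <= 0)) abort("monomorphic variant among requested columns")
  geno_weighted_sum_cpp(geno$counts, as.integer(idx) - 1L, effects,
                        st$mean, st$sd)
}

geno_n <- function(geno) geno$n
geno_m <- function(geno) geno$m
geno_ids <- function(geno) geno$ids

#' Write / read a genotype TSV container
#'
#' Variants as columns (header row of variant ids), one line per individual.
#' A sidecar `<path>.vars` file stores the PLINK .bim-like variant table
#' (chrom, id, pos, a1, a0, freq).
#'
#' @param G a `geno_matrix`.
#' @param path output file path.
#' @return `path`, invisibly (writer); a `geno_matrix` (reader).
#' @export
write_genotypes <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  readr::write_tsv(as_tibble(as.data.frame(G$counts)), path)
  readr::write_tsv(variant_table(G), paste0(path, ".vars"))
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  counts <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
  storage.mode(counts) <- "integer"
  vars <- readr::read_tsv(paste0(path, ".vars"), show_col_types = FALSE)
  structure(
    list(counts = counts, freqs = vars$freq, positions = vars$pos,
         chrom = as.character(vars$chrom), ids = vars$id,
         a1 = vars$a1, a0 = vars$a0, n = nrow(counts), m = ncol(counts)),
    class = "geno_matrix")
}

#' PLINK .bim-like variant table
#' @param G a `geno_matrix`.
#' @return tibble with chrom, id, pos, a1, a0, freq.
#' @export
variant_table <- function(G) {
  tibble(chrom = G$chrom, id = G$ids, pos = G$positions,
         a1 = G$a1, a0 = G$a0, freq = G$freqs)
}
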