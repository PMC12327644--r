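#' Single-SNP linear GWAS
#'
#' Ordinary least-squares slope of the phenotype on each centered-and-scaled
#' genotype column (intercept included), with its standard error and two-sided
#' p-value from the t approximation. No covariates are fitted.
#'
#' @param geno a `scaled_design` or `geno_matrix` (columns scaled in-sample on
#'   the fly, so the full scaled design is never materialised at large n).
#' @param y numeric phenotype vector (finite).
#' @return a `blr_sumstats` tibble: id, chrom, pos, a1, a0, freq, beta, se, n,
#'   pvalue.
#' @export
gwas_linear <- function(geno, y) {
  if (!all(is.finite(y))) abort("`y` must be finite")
  n <- geno_n(geno)
  if (length(y) != n) abort("length(y) must equal the number of samples")
  if (inherits(geno, "scaled_design")) {
    W <- geno$W
    yc <- y - mean(y)
    wy <- drop(crossprod(W, yc))
    ww <- colSums(W^2)
    if (any(ww <= 0)) abort("zero-variance column in the scaled design")
    beta <- wy / ww
    sse <- sum(yc^2) - beta * wy
    se <- sqrt(pmax(sse, 0) / (n - 2) / ww)
    meta <- list(freq = geno$freqs, chrom = geno$chrom, pos = geno$positions,
                 ids = geno$ids, a1 = rep("A", geno$m), a0 = rep("G", geno$m))
  } else {
    stopifnot(inherits(geno, "geno_matrix"))
    st <- geno_col_stats_cpp(geno$counts)
    if (any(st$sd <= 0))
      abort(sprintf("zero-variance (monomorphic) variant: %s",
                    geno$ids[which(st$sd <= 0)[1]]))
    res <- gwas_linear_geno_cpp(geno$counts, y, st$mean, st$sd)
    beta <- res$beta
    se <- res$se
    meta <- list(freq = st$mean / 2, chrom = geno$chrom, pos = geno$positions,
                 ids = geno$ids, a1 = geno$a1, a0 = geno$a0)
  }
  new_sumstats(meta, beta, se, n, pvalue = 2 * pt(-abs(beta / se), df = n - 2))
}

#' Single-SNP logistic GWAS
#'
#' Per-variant logistic regression of case/control labels on the scaled dosage
#' (intercept included), fitted by Newton-Raphson; the marginal effect is the
#' log-odds per scaled-dosage unit with its Wald standard error. Variants whose
#' fit does not converge (including detected separation) are flagged, not
#' fatal.
#'
#' @param geno a `geno_matrix` or `scaled_design`.
#' @param labels integer/logical 0-1 case labels; both classes must be present.
#' @return a `blr_sumstats` tibble with an extra `converged` column.
#' @export
gwas_logistic <- function(geno, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) abort("`labels` must be 0/1")
  if (length(unique(labels)) < 2) abort("both classes must be present in `labels`")
  n <- geno_n(geno)
  if (length(labels) != n) abort("length(labels) must equal the number of samples")
  if (inherits(geno, "scaled_design")) {
    res <- gwas_logistic_dense(geno$W, labels)
    meta <- list(freq = geno$freqs, chrom = geno$chrom, pos = geno$positions,
                 ids = geno$ids, a1 = rep("A", geno$m), a0 = rep("G", geno$m))
  } else {
    stopifnot(inherits(geno, "geno_matrix"))
    st <- geno_col_stats_cpp(geno$counts)
    if (any(st$sd <= 0))
      abort(sprintf("zero-variance (monomorphic) variant: %s",
                    geno$ids[which(st$sd <= 0)[1]]))
    res <- gwas_logistic_geno_cpp(geno$counts, labels, st$mean, st$sd, 50L, 1e-8)
    meta <- list(freq = st$mean / 2, chrom = geno$chrom, pos = geno$positions,
                 ids = geno$ids, a1 = geno$a1, a0 = geno$a0)
  }
  out <- new_sumstats(meta, res$beta, res$se, n,
                      pvalue = 2 * pnorm(-abs(res$beta / res$se)))
  out$converged <- res$converged & !res$separated
  out
}

# logistic NR on an already-scaled dense design (small m); same model as the
# integer-dosage kernel
gwas_logistic_dense <- function(W, labels) {
  m <- ncol(W)
  beta <- se <- numeric(m)
  converged <- separated <- logical(m)
  for (j in seq_len(m)) {
    w <- W[, j]
    b0 <- b1 <- 0
    for (it in 1:50) {
      eta <- b0 + b1 * w
      p <- 1 / (1 + exp(-eta))
      v <- p * (1 - p)
      S0 <- sum(v); S1 <- sum(v * w); S2 <- sum(v * w^2)
      det <- S0 * S2 - S1^2
      if (det <= 1e-12 || !is.finite(det)) { separated[j] <- TRUE; break }
      r <- labels - p
      d0 <- (S2 * sum(r) - S1 * sum(r * w)) / det
      d1 <- (S0 * sum(r * w) - S1 * sum(r)) / det
      b0 <- b0 + d0; b1 <- b1 + d1
      if (abs(b1) > 15) { separated[j] <- TRUE; break }
      if (abs(d0) < 1e-8 && abs(d1) < 1e-8) {
        converged[j] <- TRUE
        se[j] <- sqrt(S0 / det)
        break
      }
    }
    beta[j] <- b1
    if (!converged[j]) se[j] <- NA_real_
  }
  list(beta = beta, se = se, converged = converged, separated = separated)
}

new_sumstats <- function(meta, beta, se, n, pvalue) {
  out <- tibble(id = meta$ids, chrom = meta$chrom, pos = meta$pos,
                a1 = meta$a1, a0 = meta$a0, freq = unname(meta$freq),
                beta = unname(beta), se = unname(se), n = as.double(n),
                pvalue = unname(pmax(pvalue, .Machine$double.xmin)))
  class(out) <- c("blr_sumstats", class(out))
  out
}

#' Re-express marginal effects on the standardized-phenotype scale
#'
#' Converts summary statistics to the scale of a single-SNP regression of a
#' variance-1 phenotype on the scaled genotype, using only the z-statistic and
#' the sample size: \eqn{b = z / \sqrt{n - 2 + z^2}} with standard error
#' \eqn{1 / \sqrt{n - 2 + z^2}} (the exact inversion of the OLS t-statistic on
#' standardized data). For linear GWAS of an (approximately) variance-1
#' phenotype this is a near-identity; its purpose is logistic summary
#' statistics, whose log-odds effects are otherwise on the wrong scale for the
#' variance-1 sufficient-statistic reconstruction. This mirrors the common
#' practice of feeding case/control GWAS to Gaussian summary-statistic
#' fine-mappers through their z-scores.
#'
#' @param ss a `blr_sumstats` tibble.
#' @return a `blr_sumstats` tibble with rescaled `beta` and `se`.
#' @export
standardize_sumstats <- function(ss) {
  stopifnot(inherits(ss, "blr_sumstats"))
  z <- ss$beta / ss$se
  z[!is.finite(z)] <- 0  # e.g. non-converged logistic fits enter as null
  denom <- sqrt(ss$n - 2 + z^2)
  ss$beta <- z / denom
  ss$se <- 1 / denom
  ss
}

#' Compute an LD correlation matrix
#'
#' Signed Pearson correlations among genotype columns, either dense (one
#' fine-mapping region) or banded (genome-wide: entries beyond `half_bandwidth`
#' variants are implicitly zero, emulating sliding-window LD estimation).
#' Dosage columns are centered and scaled in sample, so the diagonal is exactly
#' 1 and, for a `scaled_design`, `B = W'W / n`.
#'
#' @param geno a `scaled_design` or `geno_matrix`.
#' @param half_bandwidth optional half bandwidth in variants; `NULL` gives a
#'   dense matrix. The conventional genome-wide choice for a 2,000-SNP sliding
#'   window shifting one SNP at a time is 1999.
#' @param subsample_n optionally estimate LD on a random subsample of this many
#'   individuals (common when the reference cohort is very large).
#' @param seed seed for the subsample draw.
#' @return an `ld_matrix` (dense or banded layout).
#' @export
compute_ld <- function(geno, half_bandwidth = NULL, subsample_n = NULL, seed = NULL) {
  n <- geno_n(geno)
  if (n < 2) abort("need at least 2 samples to estimate LD")
  if (!is.null(subsample_n) && subsample_n < n) {
    keep <- with_seed(seed, sort(sample.int(n, subsample_n)))
    if (inherits(geno, "geno_matrix")) {
      geno$counts <- geno$counts[keep, , drop = FALSE]
      geno$n <- length(keep)
    } else {
      geno$W <- geno$W[keep, , drop = FALSE]  # re-center below via dense path
      geno$W <- scale(geno$W, center = TRUE, scale = FALSE)
      geno$W <- sweep(geno$W, 2, sqrt(colMeans(geno$W^2)), "/")
      geno$n <- length(keep)
    }
    n <- geno_n(geno)
  }
  m <- geno_m(geno)
  if (inherits(geno, "scaled_design")) {
    B <- crossprod(geno$W) / n
    if (!is.null(half_bandwidth)) {
      hb <- assert_count(half_bandwidth, "half_bandwidth", min = 0L)
      band <- matrix(0, hb + 1, m)
      for (k in 0:hb) {
        j <- seq_len(m - k)
        band[k + 1, j] <- B[cbind(j, j + k)]
      }
      return(new_ld_matrix(band, geno$ids, "banded", hb))
    }
    return(new_ld_matrix(B, geno$ids, "dense", NULL))
  }
  stopifnot(inherits(geno, "geno_matrix"))
  st <- geno_col_stats_cpp(geno$counts)
  if (any(st$sd <= 0))
    abort(sprintf("zero-variance (monomorphic) variant: %s",
                  geno$ids[which(st$sd <= 0)[1]]))
  chunk <- max(1024L, min(geno$n, as.integer(2^26 / m)))
  if (is.null(half_bandwidth)) {
    B <- ld_geno_dense_cpp(geno$counts, st$mean, st$sd, chunk)
    new_ld_matrix(B, geno$ids, "dense", NULL)
  } else {
    hb <- assert_count(half_bandwidth, "half_bandwidth", min = 0L)
    band <- ld_geno_band_cpp(geno$counts, st$mean, st$sd, hb, chunk)
    new_ld_matrix(band, geno$ids, "banded", hb)
  }
}

new_ld_matrix <- function(values, ids, layout, half_bandwidth) {
  if (layout == "dense") dimnames(values) <- list(ids, ids)
  structure(list(r = values, ids = ids, layout = layout,
                 half_bandwidth = half_bandwidth, m = length(ids)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants, %s layout%s\n", x$m, x$layout,
              if (x$layout == "banded") sprintf(" (half bandwidth %d)", x$half_bandwidth) else ""))
  invisible(x)
}

#' @export
as.matrix.ld_matrix <- function(x, ...) {
  if (x$layout == "dense") return(x$r)
  m <- x$m
  B <- matrix(0, m, m, dimnames = list(x$ids, x$ids))
  for (k in 0:x$half_bandwidth) {
    j <- seq_len(m - k)
    B[cbind(j, j + k)] <- x$r[k + 1, j]
    B[cbind(j + k, j)] <- x$r[k + 1, j]
  }
  B
}

# subset a dense ld_matrix to a set of indices
ld_subset <- function(B, idx) {
  if (B$layout != "dense") {
    Bm <- as.matrix(B)[idx, idx, drop = FALSE]
    return(new_ld_matrix(Bm, B$ids[idx], "dense", NULL))
  }
  new_ld_matrix(B$r[idx, idx, drop = FALSE], B$ids[idx], "dense", NULL)
}

#' Reconstruct sufficient statistics from summary statistics and LD
#'
#' Rebuilds the multiple-regression sufficient statistics from marginal GWAS
#' effects and an LD correlation matrix:
#' \deqn{X'X = D^{1/2} B D^{1/2}, \quad X'y = D \tilde b,}
#' with \eqn{D_i = n_i} when the genotypes were centered and scaled (the
#' in-sample convention of this package, where the identity is exact) and
#' \eqn{D_i = 1 / (\sigma^2_{\tilde b_i} + \tilde b_i^2 / n_i)} for
#' centered-only genotypes.
#'
#' @param ss a `blr_sumstats` tibble.
#' @param B an `ld_matrix`, index-aligned with `ss` (ids must match).
#' @param scaled were the genotypes scaled to unit variance (TRUE) or centered
#'   only (FALSE)?
#' @return a `blr_suffstats` list: `XtX` (dense or banded, matching `B`),
#'   `Xty`, `D`, `n_eff` (median per-variant n), `yty` (n_eff * Var(y), with
#'   Var(y) = 1 assumed for summary data), `layout`.
#' @export
reconstruct_suffstats <- function(ss, B, scaled = TRUE) {
  stopifnot(inherits(ss, "blr_sumstats"), inherits(B, "ld_matrix"))
  if (length(B$ids) != nrow(ss) || !all(B$ids == ss$id)) {
    bad <- which(B$ids != ss$id)[1]
    abort(sprintf("summary statistics and LD matrix are misaligned (first mismatch at position %s: '%s' vs '%s')",
                  ifelse(is.na(bad), length(B$ids), bad),
                  ss$id[ifelse(is.na(bad), 1, bad)], B$ids[ifelse(is.na(bad), 1, bad)]))
  }
  D <- if (scaled) ss$n else 1 / (ss$se^2 + ss$beta^2 / ss$n)
  sD <- sqrt(D)
  if (B$layout == "dense") {
    XtX <- B$r * tcrossprod(sD)
  } else {
    XtX <- B$r
    m <- B$m
    for (k in 0:B$half_bandwidth) {
      j <- seq_len(m - k)
      XtX[k + 1, j] <- XtX[k + 1, j] * sD[j] * sD[j + k]
    }
  }
  n_eff <- median(ss$n)
  structure(list(XtX = XtX, Xty = D * ss$beta, D = D, n_eff = n_eff,
                 yty = n_eff, layout = B$layout,
                 half_bandwidth = B$half_bandwidth, ids = ss$id),
            class = "blr_suffstats")
}

#' Summary-statistics TSV I/O
#'
#' Column set: id, chrom, pos, a1, a0, freq, beta, se, n, pvalue
#' (plus `converged` for logistic scans).
#'
#' @param ss a `blr_sumstats` tibble.
#' @param path file path.
#' @export
write_sumstats <- function(ss, path) {
  readr::write_tsv(ss, path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = readr::col_character()))
  need <- c("id", "chrom", "pos", "a1", "a0", "freq", "beta", "se", "n", "pvalue")
  miss <- setdiff(need, names(out))
  if (length(miss)) abort(paste("missing summary-statistic columns:",
                                paste(miss, collapse = ", ")))
  class(out) <- c("blr_sumstats", class(out))
  out
}

#' LD matrix I/O
#'
#' Dense matrices are stored as a TSV with variant ids as the header; banded
#' matrices as (i, j, r) triplets with a one-line `#half_bandwidth` header
#' comment and a sidecar id column order preserved in the triplet file.
#'
#' @param B an `ld_matrix`.
#' @param path file path.
#' @export
write_ld <- function(B, path) {
  if (B$layout == "dense") {
    readr::write_tsv(as_tibble(as.data.frame(B$r)), path)
  } else {
    m <- B$m
    rows <- purrr::map_dfr(0:B$half_bandwidth, function(k) {
      left <- seq_len(m - k)
      tibble(i = left, j = left + k, r = B$r[k + 1, left])
    })
    readr::write_tsv(rows, path)
  }
  readr::write_tsv(tibble(id = B$ids), paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_ld
#' @param layout `"dense"` or `"banded"` (how `path` was written).
#' @param half_bandwidth required when reading a banded file.
#' @export
read_ld <- function(path, layout = c("dense", "banded"), half_bandwidth = NULL) {
  layout <- match.arg(layout)
  ids <- readr::read_tsv(paste0(path, ".ids"), show_col_types = FALSE)$id
  if (layout == "dense") {
    B <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
    return(new_ld_matrix(unname(B), ids, "dense", NULL))
  }
  if (is.null(half_bandwidth)) abort("`half_bandwidth` is required for banded layout")
  tr <- readr::read_tsv(path, show_col_types = FALSE)
  hb <- as.integer(half_bandwidth)
  band <- matrix(0, hb + 1, length(ids))
  band[cbind(tr$j - tr$i + 1L, tr$i)] <- tr$r
  new_ld_matrix(band, ids, "banded", hb)
}
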