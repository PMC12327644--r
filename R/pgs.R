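#' Polygenic score from estimated SNP effects
#'
#' Per-individual weighted sum of allele dosages,
#' \eqn{PGS_j = \sum_i x_{ji} \hat b_i}. Weights estimated on the
#' centered-and-scaled genotype scale (the default for all fits in this
#' package) are applied to the scaled dosages; `scale = "dosage"` applies them
#' to raw allele counts (equivalently, convert scaled weights with
#' \eqn{b_{raw} = b_{scaled} / \sqrt{2 p (1 - p)}}).
#'
#' @param geno validation genotypes (`geno_matrix` or `scaled_design`).
#' @param weights named numeric vector of effects, or a tibble with `id` and a
#'   weight column (`b_mean` or `weight`); ids must be present in `geno`.
#' @param scale genotype coding the weights refer to.
#' @return numeric score per validation sample.
#' @export
compute_pgs <- function(geno, weights, scale = c("scaled", "dosage")) {
  scale <- match.arg(scale)
  if (is.data.frame(weights)) {
    wcol <- intersect(c("weight", "b_mean", "effect"), names(weights))[1]
    if (is.na(wcol)) abort("`weights` tibble needs a weight/b_mean/effect column")
    w <- setNames(weights[[wcol]], weights$id)
  } else {
    if (is.null(names(weights))) abort("`weights` must be named by variant id")
    w <- weights
  }
  ids <- geno_ids(geno)
  missing_ids <- setdiff(names(w), ids)
  if (length(missing_ids))
    abort(paste("weight ids absent from genotypes:",
                paste(head(missing_ids, 5), collapse = ", ")))
  idx <- match(names(w), ids)
  if (scale == "scaled") return(geno_genetic_value(geno, idx, unname(w)))
  X <- matrix(as.double(
    if (inherits(geno, "geno_matrix")) geno$counts[, idx, drop = FALSE]
    else geno$W[, idx, drop = FALSE]), nrow = geno_n(geno))
  drop(X %*% unname(w))
}

#' Predictive R-squared of a polygenic score
#'
#' The validation phenotype is regressed on the score; the coefficient of
#' determination of that simple regression (the squared Pearson correlation)
#' measures predictive ability for quantitative traits.
#'
#' @param y validation phenotype (already covariate-adjusted/scaled if
#'   applicable).
#' @param scores polygenic scores (non-constant).
#' @return R-squared in `[0, 1]`.
#' @export
predictive_r2 <- function(y, scores) {
  if (sd(scores) == 0) abort("scores are constant; R2 undefined")
  stats::cor(y, scores)^2
}

#' Predictive AUC of a polygenic score for a binary trait
#'
#' Rank-based (Mann-Whitney) AUC of the scores against the case/control
#' labels; invariant to any strictly monotone transform of the scores.
#'
#' @param labels 0/1 case labels.
#' @param scores polygenic scores.
#' @return AUC in `[0, 1]`.
#' @export
predictive_auc <- function(labels, scores) {
  pip_auc(scores, labels)
}
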