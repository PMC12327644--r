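#' Score credible sets against the simulated truth
#'
#' Applies per-region confusion rules: a credible set containing a causal
#' (index) variant is a true positive, unless it has more than `max_tp_size`
#' variants, in which case that causal counts as a false negative (overly large
#' sets carry little fine-mapping value); a set containing no causal variant is
#' a false positive; a region that produced no set, or whose sampler failed to
#' converge, contributes a false negative per causal variant (a non-converged
#' region's sets are not counted at all). In multi-causal regions each causal
#' variant is scored independently: a set containing either causal is a true
#' positive for that causal.
#'
#' @param regions region tibble with `region_id` and either `causal_index`
#'   or a `causal_ids` list-column naming each region's causal variant ids.
#' @param credsets tibble of credible-set members with columns `region_id`,
#'   `cs_id`, `id` (as returned by [cs2()], bound over regions); may have zero
#'   rows.
#' @param truth causal-truth tibble with an `id` column (all causal variant
#'   ids); used when `regions` lacks `causal_ids`.
#' @param max_tp_size size above which a causal-containing set becomes a false
#'   negative.
#' @param convergence optional tibble (`region_id`, `converged`); missing
#'   regions are assumed converged.
#' @return list with `counts` (tibble TP, FP, FN) and `regions` (per-region
#'   labels).
#' @export
classify_regions <- function(regions, credsets, truth = NULL, max_tp_size = 10,
                             convergence = NULL) {
  if (!"causal_ids" %in% names(regions)) {
    if (is.null(truth)) abort("either regions$causal_ids or `truth` is required")
    regions$causal_ids <- purrr::map(regions$causal_index,
                                     function(i) truth$id[truth$index == i])
  }
  conv <- setNames(rep(TRUE, nrow(regions)), regions$region_id)
  if (!is.null(convergence))
    conv[convergence$region_id] <- convergence$converged
  missing_regions <- setdiff(unique(credsets$region_id), regions$region_id)
  if (length(missing_regions))
    abort(paste("credible sets reference unknown region ids:",
                paste(head(missing_regions, 5), collapse = ", ")))
  per_region <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    rid <- regions$region_id[i]
    causals <- regions$causal_ids[[i]]
    tp <- fp <- fn <- 0L
    if (!conv[[rid]]) {
      fn <- length(causals)
    } else {
      sets <- credsets[credsets$region_id == rid, , drop = FALSE]
      if (nrow(sets) == 0) {
        fn <- length(causals)
      } else {
        bysets <- split(sets$id, sets$cs_id)
        for (cz in causals) {
          hit <- vapply(bysets, function(mem) cz %in% mem, logical(1))
          if (!any(hit)) {
            fn <- fn + 1L
          } else if (min(lengths(bysets)[hit]) > max_tp_size) {
            fn <- fn + 1L  # causal found only in oversized sets
          } else {
            tp <- tp + 1L
          }
        }
        fp <- sum(vapply(bysets, function(mem) !any(causals %in% mem), logical(1)))
      }
    }
    tibble(region_id = rid, TP = tp, FP = fp, FN = fn, converged = conv[[rid]])
  })
  list(counts = tibble(TP = sum(per_region$TP), FP = sum(per_region$FP),
                       FN = sum(per_region$FN)),
       regions = per_region)
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision is TP / (TP + FP), recall is TP / (TP + FN), and F1 their
#' harmonic mean 2 p r / (p + r). Zero
#' denominators yield 0 by convention, so methods that output nothing score
#' worst.
#'
#' @param counts tibble or list with TP, FP, FN (e.g.
#'   `classify_regions()$counts`).
#' @return tibble with precision, recall, f1.
#' @export
f1_score <- function(counts) {
  tp <- counts$TP
  fp <- counts$FP
  fn <- counts$FN
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble(precision = p, recall = r, f1 = f1)
}

#' Rank-based AUC of PIPs against the causal indicator
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a randomly
#' chosen causal variant has a higher PIP than a randomly chosen non-causal
#' one (ties count 1/2).
#'
#' @param pips per-variant PIPs (any monotone score works).
#' @param causal 0/1 (or logical) truth indicator; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
pip_auc <- function(pips, causal) {
  causal <- as.logical(causal)
  n1 <- sum(causal)
  n0 <- sum(!causal)
  if (n1 == 0 || n0 == 0)
    abort("AUC undefined: both causal and non-causal variants are required")
  rk <- rank(pips)  # midranks
  (sum(rk[causal]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Geweke convergence diagnostic for an MCMC chain
#'
#' Compares the means of the first `frac_first` and last `frac_last` segments
#' of the chain; under stationarity the standardised difference is
#' asymptotically standard normal. Standard errors are
#' autocorrelation-robust by default, using the spectral density at frequency
#' zero estimated from an AR fit (`method = "spectral"`); `method = "naive"`
#' uses plain iid standard errors of the segment means.
#'
#' @param chain numeric vector of sampled values (length >= 20).
#' @param frac_first,frac_last segment fractions (defaults 0.10 and 0.50).
#' @param method `"spectral"` (default) or `"naive"`.
#' @return list with `z`, `converged` (|z| <= 3) and `assessable` (`FALSE` for
#'   zero-variance segments, where z is undefined).
#' @export
geweke_z <- function(chain, frac_first = 0.10, frac_last = 0.50,
                     method = c("spectral", "naive")) {
  method <- match.arg(method)
  n <- length(chain)
  if (n < 20) abort("chain too short for the Geweke diagnostic (need >= 20)")
  if (frac_first + frac_last > 1) abort("segment fractions must not overlap")
  a <- chain[seq_len(floor(frac_first * n))]
  b <- chain[seq.int(n - floor(frac_last * n) + 1L, n)]
  if (sd(a) == 0 || sd(b) == 0)
    return(list(z = NA_real_, converged = NA, assessable = FALSE))
  va <- if (method == "spectral") spectrum0_ar(a) else var(a)
  vb <- if (method == "spectral") spectrum0_ar(b) else var(b)
  if (!is.finite(va) || !is.finite(vb) || va <= 0 || vb <= 0)
    return(list(z = NA_real_, converged = NA, assessable = FALSE))
  z <- (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
  list(z = z, converged = abs(z) <= 3, assessable = TRUE)
}

# long-run variance: spectral density at frequency zero from an AR fit with
# AIC order selection, var.pred / (1 - sum(phi))^2
spectrum0_ar <- function(x) {
  x <- x - mean(x)
  fit <- try(ar(x, aic = TRUE, order.max = min(length(x) - 1L,
                                               floor(10 * log10(length(x))))),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(var(x))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Mean performance rank of methods across scenarios
#'
#' Within each scenario methods are ranked on the score (rank 1 = best; ties
#' get the average rank), and ranks are averaged across scenarios with a
#' standard error.
#'
#' @param metric_table tibble with one row per scenario x method.
#' @param score column name of the score (larger is better).
#' @param method,scenario column names identifying method and scenario.
#' @return tibble: method, mean_rank, se_rank, n_scenarios.
#' @export
rank_methods <- function(metric_table, score = "f1", method = "method",
                         scenario = "scenario") {
  tab <- metric_table[, c(scenario, method, score)]
  names(tab) <- c("scenario", "method", "score")
  full <- tidyr::expand_grid(scenario = unique(tab$scenario),
                             method = unique(tab$method))
  missing <- dplyr::anti_join(full, tab, by = c("scenario", "method"))
  if (nrow(missing))
    abort(paste("missing scenario x method cells:",
                paste(head(sprintf("%s/%s", missing$scenario, missing$method), 5),
                      collapse = ", ")))
  tab |>
    dplyr::group_by(.data$scenario) |>
    dplyr::mutate(rnk = rank(-.data$score)) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_rank = mean(.data$rnk),
                     se_rank = sd(.data$rnk) / sqrt(dplyr::n()),
                     n_scenarios = dplyr::n(), .groups = "drop")
}
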