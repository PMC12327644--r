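#' Plot per-variant posterior inclusion probabilities
#'
#' Locus-style plot of PIP against variant index, highlighting any variants
#' listed in `highlight` (e.g. the simulated causal ids).
#'
#' @param object a `blr_fit`.
#' @param highlight optional variant ids drawn in a distinct colour.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot blr_fit
#' @export
autoplot.blr_fit <- function(object, highlight = NULL, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  d$status <- ifelse(d$id %in% highlight, "highlighted", "other")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$pip,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(highlighted = "#d43f3a",
                                            other = "grey40"),
                                 guide = if (is.null(highlight)) "none" else "legend") +
    ggplot2::labs(x = "variant", y = "posterior inclusion probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Trace plots of the sampled hyperparameter chains
#'
#' @param fit a `blr_fit`.
#' @param params chain columns to show.
#' @return a ggplot object.
#' @export
plot_trace <- function(fit, params = c("sigma_b2", "sigma_e2", "sigma_g2")) {
  stopifnot(inherits(fit, "blr_fit"))
  d <- purrr::imap_dfr(fit$chains, function(ch, r) {
    ch$iteration <- seq_len(nrow(ch))
    ch$run <- factor(r)
    ch
  })
  d <- tidyr::pivot_longer(d, dplyr::all_of(params), names_to = "param")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value,
                                  colour = .data$run)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style summary of scenario metrics by method
#'
#' @param metrics output of [run_scenario()] (possibly row-bound over
#'   scenarios).
#' @param score metric column to summarise.
#' @return a ggplot object.
#' @export
plot_metrics <- function(metrics, score = "f1") {
  d <- metrics |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean = mean(.data[[score]], na.rm = TRUE),
                     se = sd(.data[[score]], na.rm = TRUE) /
                       sqrt(sum(is.finite(.data[[score]]))),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean,
                                  y = stats::reorder(.data$method, .data$mean))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean - .data$se,
                                         xmax = .data$mean + .data$se),
                            height = 0.2) +
    ggplot2::labs(x = score, y = NULL) +
    ggplot2::theme_minimal()
}
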