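#' Tidy a random-intercept logistic fit
#'
#' One row per fixed-effect term with the cluster-robust standard error,
#' odds ratio, and 95% Wald confidence interval.
#'
#' @param x An `evoc_fit` from [fit_hier_logit()].
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate` (log odds), `std.error` (robust),
#'   `statistic`, `p.value`, `or`, `conf_low`, `conf_high` (OR scale).
#' @export
tidy.evoc_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_robust))
  z <- qnorm(1 - (1 - conf_level) / 2)
  stat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pnorm(-abs(stat))),
    or = exp(.data$estimate),
    conf_low = exp(.data$estimate - z * se),
    conf_high = exp(.data$estimate + z * se)
  )
}

#' @export
glance.evoc_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_clusters = x$n_clusters, re_sd = x$re_sd,
    converged = x$converged, method = x$method
  )
}

#' Tidy a Rubin-pooled fit
#'
#' @param x An `evoc_pooled` from [pool_rubin()].
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error` (total pooled),
#'   `statistic`, `df`, `p.value`, `or`, `conf_low`, `conf_high` (OR scale).
#' @export
tidy.evoc_pooled <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    df = unname(x$df),
    p.value = unname(x$p.value),
    or = exp(.data$estimate),
    conf_low = unname(exp(x$conf_low)),
    conf_high = unname(exp(x$conf_high))
  )
}

#' @export
glance.evoc_pooled <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_clusters = x$n_clusters, m = x$m, re_sd = x$re_sd,
    converged = x$converged
  )
}

#' Forest plot of pooled joint-exposure odds ratios
#'
#' @param object An `evoc_pooled` fit.
#' @param terms Regular expression selecting terms to display (default: the
#'   joint-category contrasts).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evoc_pooled <- function(object, terms = "^category", ...) {
  d <- tidy(object) |>
    dplyr::filter(grepl(terms, .data$term)) |>
    dplyr::mutate(term = sub(terms, "", .data$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$conf_low, xmax = .data$conf_high
    )) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (95% CI, log scale)", y = NULL,
      title = "Adjusted odds ratios vs reference category"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-VOC joint-category odds ratios
#'
#' @param results The `results` tibble from [fit_joint_models()].
#' @param window Exposure window to display.
#' @return A ggplot object faceted by joint category.
#' @export
plot_joint_ors <- function(results, window = "preconception") {
  d <- dplyr::filter(results, .data$window == !!window)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$voc,
    colour = .data$bh_significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$conf_low, xmax = .data$conf_high
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$category)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
      name = "BH significant"
    ) +
    ggplot2::labs(
      x = "Odds ratio (95% CI, log scale)", y = NULL,
      title = paste("GDM odds ratios,", window, "window"),
      subtitle = "Reference: Low VOC / Enclave"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the VOC Spearman correlation matrix
#'
#' @param rho Matrix from [spearman_voc_matrix()].
#' @return A ggplot object.
#' @export
plot_voc_correlation <- function(rho) {
  d <- as.data.frame(as.table(rho))
  names(d) <- c("voc1", "voc2", "rho")
  ggplot2::ggplot(d, ggplot2::aes(.data$voc1, .data$voc2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      limits = c(-1, 1), low = "steelblue", mid = "white", high = "firebrick"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
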