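#' Distribution plot of speed and accuracy by tracking mode
#'
#' Violin-style distributions of tracking speed `S` and log accuracy
#' `log10(A)` per mode, with the quartiles marked (median solid,
#' Q25/Q75 dashed).
#'
#' @param metrics Per-frame metrics tibble with `mode`, `S` and `A`.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(metrics) {
  long <- metrics %>%
    mutate(`log10(A)` = log10(.data$A)) %>%
    select("mode", S = "S", `log10(A)` = "log10(A)") %>%
    tidyr::pivot_longer(-"mode", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mode, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::stat_summary(fun = median, geom = "crossbar",
                          width = 0.5, linewidth = 0.4) +
    ggplot2::stat_summary(
      fun = function(z) quantile(z, 0.25), geom = "crossbar",
      width = 0.35, linetype = "dashed", linewidth = 0.25) +
    ggplot2::stat_summary(
      fun = function(z) quantile(z, 0.75), geom = "crossbar",
      width = 0.35, linetype = "dashed", linewidth = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tracking speed and accuracy by mode",
                  subtitle = "simulated-agent data") +
    ggplot2::theme_minimal()
}

#' Paired differences against point velocity
#'
#' Scatter of `delta_S` or `delta_A` against point velocity `V`,
#' optionally overlaid with the posterior mean curve and 89% band of a
#' fitted piecewise model per group.
#'
#' @param deltas Paired-differences tibble from [paired_deltas()].
#' @param outcome `"delta_S"` or `"delta_A"`.
#' @param fit Optional `piecewise_fit` on the same outcome.
#' @return A ggplot object.
#' @export
plot_delta_vs_velocity <- function(deltas, outcome = c("delta_S", "delta_A"),
                                   fit = NULL) {
  outcome <- match.arg(outcome)
  p <- ggplot2::ggplot(
    deltas, ggplot2::aes(x = .data$V, y = .data[[outcome]])) +
    ggplot2::geom_point(alpha = 0.1, size = 0.4, colour = "grey40") +
    ggplot2::labs(x = "point velocity V [px/frame]", y = outcome,
                  subtitle = "simulated-agent data") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + fit_band_layers(fit)
  }
  p
}

fit_band_layers <- function(fit, conf_level = 0.89, n_grid = 100L) {
  a <- (1 - conf_level) / 2
  grid_v <- seq(min(fit$data$V), max(fit$data$V), length.out = n_grid)
  band <- purrr::map_dfr(fit$groups, function(grp) {
    mu <- posterior_mu(fit, grid_v, grp)
    tibble(group = grp, V = grid_v,
           mean = colMeans(mu),
           lo = apply(mu, 2, quantile, a),
           hi = apply(mu, 2, quantile, 1 - a))
  })
  list(
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$V, ymin = .data$lo, ymax = .data$hi,
                   fill = .data$group),
      alpha = 0.3, inherit.aes = FALSE),
    ggplot2::geom_line(
      data = band,
      ggplot2::aes(x = .data$V, y = .data$mean, colour = .data$group),
      inherit.aes = FALSE)
  )
}

#' @describeIn fit_piecewise Plot the data with posterior mean curves
#'   and 89% bands per group.
#' @param object A `piecewise_fit`.
#' @param ... Unused.
#' @export
autoplot.piecewise_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$V, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.1, size = 0.4, colour = "grey40") +
    fit_band_layers(object) +
    ggplot2::labs(x = "point velocity V [px/frame]", y = object$outcome,
                  title = sprintf("Piecewise fit (%s, %s variant)",
                                  object$outcome, object$variant)) +
    ggplot2::theme_minimal()
}
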