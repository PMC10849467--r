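# ggplot2 autoplot methods for the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pre-training loss history
#'
#' @param object A `grf_pretrain_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grf_pretrain_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "backpropagation step", y = "training loss (MSE)",
                  title = paste(object$objective, "pre-training")) +
    ggplot2::theme_minimal()
}

#' Plot per-participant evaluation metrics
#'
#' Per-axis correlation between estimated and gold GRF, one point per
#' participant.
#'
#' @param object A `grf_eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grf_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_axis,
                  ggplot2::aes(x = .data$axis, y = .data$rho)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08,
                                                            seed = 1),
                        alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "#d95f02") +
    ggplot2::labs(x = "GRF axis", y = expression(rho),
                  title = "GRF estimation accuracy per participant") +
    ggplot2::theme_minimal()
}

#' Plot a data-efficiency scaling curve
#'
#' @param object A `grf_scaling_curve` from [scaling_curve()].
#' @param log_x Use a log10 x axis (for the exponential fraction grid).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grf_scaling_curve <- function(object, log_x = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction,
                                            y = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of labeled training data", y = "metric",
                  title = "data-efficiency scaling curve") +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a masking-ratio x patch-length grid
#'
#' @param object A `grf_grid` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot tile map of downstream correlation.
#' @export
autoplot.grf_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$masking_ratio),
                               y = factor(.data$patch_length),
                               fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "masking ratio", y = "patch length",
                  fill = expression(rho),
                  title = "downstream accuracy across the masking grid") +
    ggplot2::theme_minimal()
}

#' Plot a spectrum-error curve
#'
#' @param object The `spectrum` tibble of a `grf_eval_report`, or the report
#'   itself.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_spectrum_error <- function(object, ...) {
  df <- if (inherits(object, "grf_eval_report")) object$spectrum else object
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "frequency (Hz)", y = "mean spectrum error",
                  title = "estimated minus gold GRF magnitude spectrum") +
    ggplot2::theme_minimal()
}
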