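#' Plot a Welch power spectral density
#'
#' @param object A `psd_tbl` from [welch_psd()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(paste("density (", mu * V^2, "/Hz)"))) +
    ggplot2::theme_minimal()
}

#' Plot an importance report as a percent-contribution bar chart
#'
#' @param object An `importance_report`.
#' @param k Number of top features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, k = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), k)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$percent, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "contribution (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pooled out-of-fold predictions against observed improvements
#'
#' Shows the selected model's pooled cross-validated predictions versus the
#' observed per-item improvement (negative = improvement), with the lasso
#' calibration line.
#'
#' @param object A `model_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_result <- function(object, ...) {
  df <- object$predictions
  cal <- calibrate(df$prediction, df$outcome)
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$outcome)) +
    ggplot2::geom_jitter(height = 0.12, width = 0, alpha = 0.5) +
    ggplot2::geom_abline(intercept = cal$intercept, slope = cal$slope,
                         linetype = 2) +
    ggplot2::labs(
      x = "pooled out-of-fold prediction",
      y = "observed improvement (week 8 - baseline)",
      title = sprintf("%s: C index %.3f (%.3f-%.3f)", object$symptom,
                      object$c_index, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
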