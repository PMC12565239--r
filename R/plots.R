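#' @importFrom ggplot2 autoplot ggplot aes geom_line facet_wrap labs
#'   scale_fill_viridis_c geom_col theme_minimal
NULL

#' Plot a recording's two channels
#'
#' @param object An `eog_recording`.
#' @param ... Unused.
#' @return A ggplot of horizontal and vertical traces over time.
#' @export
autoplot.eog_recording <- function(object, ...) {
  n <- length(object$horizontal)
  df <- tibble(
    time = rep((seq_len(n) - 1) / object$sampling_rate, 2),
    amplitude = c(object$horizontal, object$vertical),
    channel = rep(c("horizontal", "vertical"), each = n)
  )
  ggplot(df, aes(x = .data$time, y = .data$amplitude)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "amplitude (signal units)",
         title = sprintf("%s (%s), text %d", object$subject_id,
                         object$group_label, object$text_meta$text_id)) +
    theme_minimal()
}

#' Plot an energy scalogram
#'
#' @param object An `eog_scalogram`.
#' @param ... Unused.
#' @return A ggplot raster of log10 power over time and frequency.
#' @export
autoplot.eog_scalogram <- function(object, ...) {
  df <- expand.grid(time = (seq_len(ncol(object$power)) - 1) / object$fs,
                    frequency = object$frequencies)
  df$log_power <- as.vector(t(log10(object$power + 1e-12)))
  # frequencies are log-spaced, so tiles rather than a raster
  ggplot(df, aes(x = .data$time, y = .data$frequency, fill = .data$log_power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_continuous(trans = "log2") +
    scale_fill_viridis_c(name = "log10 power") +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot per-fold cross-validation accuracy
#'
#' @param object An `eog_cv` report.
#' @param ... Unused.
#' @return A ggplot bar chart of fold accuracies.
#' @export
autoplot.eog_cv <- function(object, ...) {
  ggplot(object$fold_metrics, aes(x = factor(.data$fold), y = .data$accuracy)) +
    geom_col() +
    labs(x = "fold", y = "accuracy (%)") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
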