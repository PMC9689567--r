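#' Plot a recording channel with its detected lift intervals
#'
#' @param recording A [lift_recording()].
#' @param rois Optional ROI tibble (from [segment_recording()]).
#' @param channel Channel to draw (default `"ax"`).
#' @return A ggplot object.
#' @export
plot_segmentation <- function(recording, rois = NULL, channel = "ax") {
  stopifnot(inherits(recording, "lift_recording"))
  df <- tibble::tibble(t = recording$t, value = recording[[channel]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(
      x = "time [s]",
      y = sprintf("%s [%s]", channel,
                  if (startsWith(channel, "a")) "m/s²" else "rad/s"),
      title = sprintf("Subject %s, trial %s", attr(recording, "subject_id"),
                      attr(recording, "trial_label"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(rois) && nrow(rois)) {
    p <- p + ggplot2::geom_rect(
      data = rois,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' Volcano-style overview of the feature screening
#'
#' Standardised class difference against -log10 p-value for the 114
#' features, coloured by significance.
#'
#' @param object A `lift_screen` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lift_screen <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    effect = (.data$mean_risk - .data$mean_no_risk) /
      pmax((.data$sd_risk + .data$sd_no_risk) / 2, .Machine$double.eps),
    neglog_p = -log10(pmax(.data$p_value, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$neglog_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "standardised difference (RISK - NO_RISK)",
                  y = expression(-log[10](p)),
                  colour = sprintf("p < %.2f", alpha)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map of a fitted risk classifier
#'
#' @param object A `lift_model` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lift_model <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    truth = rep(rownames(cm), each = 2),
    predicted = rep(colnames(cm), 2),
    n = as.vector(t(cm))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(
      title = sprintf("%s: accuracy %.1f%%", object$protocol, object$accuracy),
      x = "predicted class", y = "true class"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
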