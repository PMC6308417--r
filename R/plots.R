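#' Plot a GRF series with detected gait events
#'
#' @param series A [grf_series()].
#' @param events Optional `gait_events` to overlay (foot-strikes as solid,
#'   toe-offs as dashed vertical lines; invalid strides dimmed).
#' @param window_s Optional length-2 time window to zoom into.
#' @return A ggplot object.
#' @export
plot_grf <- function(series, events = NULL, window_s = NULL) {
  df <- tibble::as_tibble(series)
  if (!is.null(window_s)) {
    df <- df[df$time_s >= window_s[1] & df$time_s <= window_s[2], ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$force)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time [s]",
      y = sprintf("Vertical GRF [%s]",
                  if (grf_units(series) == "N") "N" else "BW"),
      title = sprintf("%s foot", grf_side(series))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- tibble::as_tibble(events)
    if (!is.null(window_s)) {
      ev <- ev[ev$foot_strike_s >= window_s[1] & ev$foot_strike_s <= window_s[2], ]
    }
    p <- p +
      ggplot2::geom_vline(data = ev,
        ggplot2::aes(xintercept = .data$foot_strike_s, alpha = .data$valid),
        colour = "#2166ac") +
      ggplot2::geom_vline(data = ev,
        ggplot2::aes(xintercept = .data$toe_off_s, alpha = .data$valid),
        colour = "#b2182b", linetype = "dashed") +
      ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.8, `FALSE` = 0.25),
                                  guide = "none")
  }
  p
}

#' Plot average stance-cycle GRF curves
#'
#' The group-level M-shape: pointwise mean force over the 0-100% stance
#' grid, optionally one curve per group.
#'
#' @param cycles A [segment_stance_cycles()] result, or a tibble with
#'   columns `stance_pct`, `force_bw` and optionally `group`.
#' @return A ggplot object.
#' @export
plot_average_cycle <- function(cycles) {
  df <- if (inherits(cycles, "stance_cycles")) average_cycle(cycles)
        else tibble::as_tibble(cycles)
  aes <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data$stance_pct, y = .data$force_bw,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$stance_pct, y = .data$force_bw)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Stance cycle [%]", y = "Vertical GRF [BW]") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix tile plot for a classification report
#'
#' @param object A [loo_cross_validate()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_loo_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      title = sprintf("LOO-LDA confusion matrix%s (ACC %.1f%%)",
                      if (is.na(object$dataset_id)) ""
                      else paste0(", dataset ", object$dataset_id),
                      object$metrics$acc),
      x = "Predicted group", y = "True group"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
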