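# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Polar histogram of stimulation phases
#'
#' The 72-bin (5-degree) circular histogram of pulse phases, with 90 degrees
#' at the up-state peak and the 45-degree ascending target marked.
#'
#' @param object A `circular_summary` from [phase_accuracy()].
#' @param target_deg Target phase to mark (default 45).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circular_summary
#' @export
autoplot.circular_summary <- function(object, target_deg = 45, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start_deg + 2.5, y = .data$count)) +
    ggplot2::geom_col(width = 5, fill = "steelblue", colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = target_deg, colour = "red", linetype = 2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "pulses",
                  title = sprintf("n = %d, mean = %.0f deg, sd = %.0f deg",
                                  object$n, object$mean_deg, object$sd_deg)) +
    ggplot2::theme_minimal()
}

#' ERP traces per condition
#'
#' @param object An `erp_result` from [erp_average()].
#' @param ... Unused.
#' @return A ggplot (mean with a +/- SD ribbon per arm).
#' @method autoplot erp_result
#' @export
autoplot.erp_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean_uv,
                                       colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_uv - .data$sd_uv,
                                      ymax = .data$mean_uv + .data$sd_uv),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time from trigger (s)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}

#' Hypnogram step plot
#'
#' @param hypnogram A `hypnogram`.
#' @param events Optional stim log; pulse times are marked under the trace.
#' @return A ggplot.
#' @export
plot_hypnogram <- function(hypnogram, events = NULL) {
  depth <- c(W = 4, REM = 3, N1 = 2, N2 = 1, N3 = 0)
  df <- dplyr::mutate(hypnogram, y = depth[.data$stage], hours = .data$onset_s / 3600)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = unname(depth), labels = names(depth)) +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events))
    p <- p + ggplot2::geom_point(data = dplyr::mutate(events, hours = .data$time_s / 3600),
                                 ggplot2::aes(x = .data$hours, y = -0.4),
                                 shape = "|", colour = "red", inherit.aes = FALSE)
  p
}

#' Quality-trace plot
#'
#' Both channels' quality indices and the selected channel over the night.
#'
#' @param quality Quality tibble (`time_s`, `q1`, `q2`, `s`).
#' @return A ggplot.
#' @export
plot_quality_trace <- function(quality) {
  long <- tidyr::pivot_longer(quality, c("q1", "q2"), names_to = "channel",
                              values_to = "q")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s / 3600, y = .data$q,
                                     colour = .data$channel)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::labs(x = "time (h)", y = "quality index") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
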