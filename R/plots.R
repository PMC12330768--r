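# ggplot2 displays for the package's result types.

#' Plot a perievent curve with its Monte-Carlo band
#'
#' Observed probability per bin with the shuffle-derived 95% band (when
#' present, i.e. after [null_band()]).
#'
#' @param object A [perievent_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.perievent_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center_s,
                                            y = .data$prob))
  if (all(c("lower", "upper") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from trigger (s)", y = "Probability")
}

#' Plot a log-survivor curve of inter-event intervals
#'
#' @param object A [log_survivor()] curve.
#' @param ... Unused.
#' @return A ggplot with a log10 ordinate.
#' @exportS3Method ggplot2::autoplot
autoplot.survivor_curve <- function(object, ...) {
  d <- object[object$survivor > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval_s, y = .data$survivor)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Inter-event interval (s)", y = "P(interval > t)")
}

#' Plot window-level twitch counts against delta power
#'
#' One panel per infant with its least-squares line — the per-infant
#' regression view of the delta-twitch association.
#'
#' @param windows A window table (`infant_id`, `mean_delta_uv2`,
#'   `n_twitches`).
#' @return A ggplot.
#' @export
plot_delta_twitch <- function(windows) {
  ggplot2::ggplot(windows, ggplot2::aes(x = .data$mean_delta_uv2,
                                        y = .data$n_twitches)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~infant_id, scales = "free_x") +
    ggplot2::labs(x = expression("Mean delta power (" * mu * V^2 * ")"),
                  y = "Twitches per window")
}

#' Plot a hypnogram
#'
#' @param hyp A [hypnogram()].
#' @return A ggplot step display of stage over time.
#' @export
plot_hypnogram <- function(hyp) {
  lv <- c("W", "REM", "N1", "N2", "N3")
  d <- dplyr::mutate(tibble::as_tibble(hyp),
                     stage_f = factor(.data$stage, levels = lv),
                     t_min = .data$onset_s / 60)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min, y = .data$stage_f,
                                  group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (min)", y = NULL)
}
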