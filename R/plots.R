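#' Plot a sleep timecourse
#'
#' The standard sleep profile: minutes of sleep per 30-minute ZT bin,
#' averaged over flies and days, with the dark phase shaded.
#'
#' @param timecourse Output of [sleep_timecourse()].
#' @param schedule A [light_schedule()] (for the dark-phase shading).
#' @return A ggplot object.
#' @export
plot_sleep_timecourse <- function(timecourse, schedule = light_schedule()) {
  avg <- timecourse |>
    dplyr::group_by(.data$zt_bin_min) |>
    dplyr::summarise(
      mean_sleep = mean(.data$sleep_min),
      # SEM is 0, not NA, for a single fly-day so the ribbon stays drawable
      sem = ifelse(dplyr::n() > 1, sd(.data$sleep_min) / sqrt(dplyr::n()), 0),
      .groups = "drop"
    )
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$zt_bin_min / 60,
                                    y = .data$mean_sleep)) +
    ggplot2::annotate("rect", xmin = schedule$photoperiod_min / 60,
                      xmax = schedule$cycle_min / 60, ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_sleep - .data$sem,
                                      ymax = .data$mean_sleep + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Sleep (min / 30 min)") +
    ggplot2::theme_classic()
}

#' Plot a place-preference occupancy heatmap
#'
#' Time of day on the abscissa, tube section on the ordinate (food-adjacent
#' section at the top), dwell time as intensity. Dwell is averaged per fly
#' when `pooled = FALSE` (the default), or summed across flies when
#' `pooled = TRUE` — both views are legitimate and differ only by a factor
#' when fly numbers are balanced.
#'
#' @param occ Occupancy tibble from [occupancy()].
#' @param pooled Sum across flies instead of averaging.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occ, pooled = FALSE) {
  agg <- occ |>
    dplyr::group_by(.data$section, .data$bin_start_min) |>
    dplyr::summarise(
      dwell = if (pooled) sum(.data$seconds) else mean(.data$seconds),
      .groups = "drop"
    )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$bin_start_min / 60,
                                    y = factor(.data$section),
                                    fill = .data$dwell)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (pooled) "s (pooled)" else "s") +
    ggplot2::labs(x = "Time (h)", y = "Tube section (10 = food)") +
    ggplot2::theme_classic()
}

#' Plot binned distance or speed
#'
#' @param distances Output of [distance_series()] (or [speed_series()]).
#' @param what Column to plot: `"distance_mm"` or `"speed_mm_s"`.
#' @return A ggplot object.
#' @export
plot_distance <- function(distances, what = "distance_mm") {
  avg <- distances |>
    dplyr::group_by(.data$bin_start_min) |>
    dplyr::summarise(v = mean(.data[[what]]), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$bin_start_min / 60,
                                    y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)",
                  y = if (what == "distance_mm") "Distance (mm/bin)"
                      else "Speed (mm/s)") +
    ggplot2::theme_classic()
}

#' Plot percentage of population active
#'
#' @param pa Output of [percent_active()].
#' @return A ggplot object.
#' @export
plot_percent_active <- function(pa) {
  ggplot2::ggplot(pa, ggplot2::aes(x = .data$bin_start_min / 60,
                                   y = .data$percent_active)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "Time (h)", y = "% flies active") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a sleep summary
#'
#' Bar chart of group means with SEM error bars, one panel per metric.
#'
#' @param object A `sleep_summary` from [average_across_days()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sleep_summary <- function(object, ...) {
  ggplot2::ggplot(object$group,
                  ggplot2::aes(x = .data$period, y = .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Analysis period", y = "Group mean ± SEM") +
    ggplot2::theme_classic()
}
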