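#' Per-bin distance travelled
#'
#' Sums full 2-D Euclidean displacements between consecutive valid 1 Hz
#' records into ZT-aligned bins, converted to mm through the tube-axis
#' calibration. Steps whose pixel displacement exceeds `max_px` are tracking
#' artifacts and contribute zero distance (they are excluded, not
#' interpolated); steps across invalid records are skipped. Only complete
#' bins are kept.
#'
#' @param traj Track-record tibble (`fly_id`, `t`, `x`, `y`, optional
#'   `valid`).
#' @param cal A [calibration()].
#' @param schedule A [light_schedule()].
#' @param bin_s Bin length, seconds (default 60).
#' @param max_px Artifact cutoff in pixels (default `Inf`, no screening;
#'   use `fbl_threshold(cal$fbl_px, 1.5)` for the 150% FBL rule).
#' @return Tibble `fly_id`, `bin_start_min`, `day`, `period`,
#'   `distance_mm`.
#' @export
distance_series <- function(traj, cal, schedule, bin_s = 60, max_px = Inf) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  if (!"valid" %in% names(traj)) traj$valid <- TRUE
  steps <- traj |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      d_px = displacement(dplyr::lag(.data$x), dplyr::lag(.data$y),
                          .data$x, .data$y),
      pair_ok = .data$valid & dplyr::lag(.data$valid, default = FALSE) &
        dplyr::coalesce(.data$t - dplyr::lag(.data$t), -1) == 1,
      step_px = dplyr::if_else(
        .data$pair_ok & !is.na(.data$d_px) & .data$d_px <= max_px,
        .data$d_px, 0),
      bin = (.data$t - schedule$lights_on_s) %/% bin_s
    ) |>
    dplyr::ungroup()
  check_entrained(steps$t, schedule)
  steps |>
    dplyr::group_by(.data$fly_id, .data$bin) |>
    dplyr::summarise(distance_mm = px_to_mm(sum(.data$step_px), cal),
                     n_s = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_s == bin_s) |>
    dplyr::mutate(
      bin_start_min = .data$bin * bin_s / 60,
      day = as.integer(.data$bin_start_min %/% schedule$cycle_min),
      period = period_of_zt(.data$bin_start_min %% schedule$cycle_min,
                            schedule)
    ) |>
    dplyr::select("fly_id", "bin_start_min", "day", "period", "distance_mm")
}

#' Total distance per day
#'
#' @param distances Output of [distance_series()].
#' @return Tibble `fly_id`, `day`, `distance_mm`.
#' @export
distance_per_day <- function(distances) {
  distances |>
    dplyr::group_by(.data$fly_id, .data$day) |>
    dplyr::summarise(distance_mm = sum(.data$distance_mm), .groups = "drop")
}

#' Total distance at a reduced capture rate
#'
#' Decimates the 1 Hz trajectory to every `stride_s`-th sample and sums the
#' polyline distance over the retained samples. By the triangle inequality
#' this never exceeds the 1 Hz total, and is strictly smaller whenever the
#' path between retained samples is not collinear — lower capture rates miss
#' distance whenever the fly reverses direction between samples.
#'
#' @param traj Track-record tibble.
#' @param cal A [calibration()].
#' @param stride_s Positive integer decimation stride in seconds; 1 returns
#'   the full-rate total.
#' @return Total distance in mm over the decimated samples.
#' @export
subsample_distance <- function(traj, cal, stride_s) {
  if (length(stride_s) != 1 || stride_s < 1 || stride_s != round(stride_s)) {
    stop("stride_s must be a positive integer", call. = FALSE)
  }
  if (!"valid" %in% names(traj)) traj$valid <- TRUE
  tot <- traj |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::filter((.data$t - min(.data$t)) %% stride_s == 0) |>
    dplyr::mutate(
      d_px = displacement(dplyr::lag(.data$x), dplyr::lag(.data$y),
                          .data$x, .data$y),
      pair_ok = .data$valid & dplyr::lag(.data$valid, default = FALSE) &
        dplyr::coalesce(.data$t - dplyr::lag(.data$t), -1) == stride_s
    ) |>
    dplyr::summarise(
      d = sum(.data$d_px[.data$pair_ok], na.rm = TRUE), .groups = "drop"
    )
  px_to_mm(sum(tot$d), cal)
}

#' Convert binned distances to speeds
#'
#' @param distances Output of [distance_series()].
#' @param bin_s Bin length the distances were computed with, seconds.
#' @return The input with a `speed_mm_s` column (`distance_mm / bin_s`).
#' @export
speed_series <- function(distances, bin_s = 60) {
  dplyr::mutate(distances, speed_mm_s = .data$distance_mm / bin_s)
}

#' Percentage of the population active per bin
#'
#' A fly counts as active in a bin when any of its seconds in that bin
#' scores a movement; the result is the percentage of flies active, per
#' ZT-aligned bin.
#'
#' @param activity Multi-fly tibble from [classify_movement()].
#' @param schedule A [light_schedule()].
#' @param bin_s Bin length, seconds (default 1800).
#' @return Tibble `bin_start_min`, `day`, `period`, `n_flies`,
#'   `percent_active` in `[0, 100]`. Complete bins only.
#' @export
percent_active <- function(activity, schedule, bin_s = 1800) {
  if (nrow(activity) == 0) stop("empty population", call. = FALSE)
  check_entrained(activity$t, schedule)
  activity |>
    dplyr::mutate(bin = (.data$t - schedule$lights_on_s) %/% bin_s) |>
    dplyr::group_by(.data$fly_id, .data$bin) |>
    dplyr::summarise(active = any(.data$moving == 1), n_s = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_s == bin_s) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_flies = dplyr::n(),
                     percent_active = 100 * mean(.data$active),
                     .groups = "drop") |>
    dplyr::mutate(
      bin_start_min = .data$bin * bin_s / 60,
      day = as.integer(.data$bin_start_min %/% schedule$cycle_min),
      period = period_of_zt(.data$bin_start_min %% schedule$cycle_min,
                            schedule)
    ) |>
    dplyr::select("bin_start_min", "day", "period", "n_flies",
                  "percent_active")
}

#' Place-preference occupancy: dwell seconds per tube section per time bin
#'
#' Each valid tracked second is assigned to one of `n_sections` equal tube
#' sections (section `n_sections` abuts the food) and one ZT-aligned time
#' bin. Optionally restricted to seconds in a sleep or wake state, using
#' minute-level sleep bouts.
#'
#' @param traj Track-record tibble for one or more flies.
#' @param cal A [calibration()].
#' @param schedule A [light_schedule()].
#' @param bin_s Time-bin length, seconds (default 60).
#' @param n_sections Number of tube sections (default 10).
#' @param state_filter `"none"`, `"asleep"` or `"awake"`; states require
#'   `bouts`.
#' @param bouts Sleep bouts from [find_sleep_bouts()] (required unless
#'   `state_filter = "none"`).
#' @return Long tibble `fly_id`, `section`, `bin_start_min`, `seconds`,
#'   with zero cells present so that section profiles are dense. The sum of
#'   `seconds` over sections in one bin equals the number of valid tracked
#'   seconds (in the requested state) in that bin.
#' @export
occupancy <- function(traj, cal, schedule, bin_s = 60, n_sections = 10,
                      state_filter = c("none", "asleep", "awake"),
                      bouts = NULL) {
  state_filter <- match.arg(state_filter)
  if (state_filter != "none" && is.null(bouts)) {
    stop("state-conditioned occupancy requires sleep bouts; ",
         "run find_sleep_bouts() first", call. = FALSE)
  }
  if (!"valid" %in% names(traj)) traj$valid <- TRUE
  check_entrained(traj$t, schedule)
  dat <- traj |>
    dplyr::filter(.data$valid) |>
    dplyr::mutate(
      section = section_of(axis_position(.data$x, .data$y, cal), cal,
                           n_sections),
      bin = (.data$t - schedule$lights_on_s) %/% bin_s,
      minute = exp_minute(.data$t, schedule)
    )
  # the grid covers every tracked bin regardless of the state filter, so
  # asleep + awake matrices partition the unconditioned one cell-wise
  all_ids <- unique(dat$fly_id)
  all_bins <- sort(unique(dat$bin))
  if (state_filter != "none") {
    dat <- dat |>
      dplyr::group_by(.data$fly_id) |>
      dplyr::group_modify(function(df, key) {
        b <- bouts[bouts$fly_id == key$fly_id, ]
        df$asleep <- minutes_in_bouts(df$minute, b)
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::filter(if (state_filter == "asleep") .data$asleep
                    else !.data$asleep)
  }
  dat |>
    dplyr::count(.data$fly_id, .data$section, .data$bin, name = "seconds") |>
    tidyr::complete(fly_id = all_ids, section = seq_len(n_sections),
                    bin = all_bins, fill = list(seconds = 0L)) |>
    dplyr::mutate(bin_start_min = .data$bin * bin_s / 60) |>
    dplyr::select("fly_id", "section", "bin_start_min", "seconds")
}

#' Collapse an occupancy table to per-section fractions
#'
#' @param occ Occupancy tibble from [occupancy()].
#' @return Tibble `section`, `seconds`, `fraction`; fractions sum to 1.
#' @export
occupancy_proportions <- function(occ) {
  out <- occ |>
    dplyr::group_by(.data$section) |>
    dplyr::summarise(seconds = sum(.data$seconds), .groups = "drop")
  tot <- sum(out$seconds)
  if (tot == 0) stop("empty occupancy: no dwell time", call. = FALSE)
  dplyr::mutate(out, fraction = .data$seconds / tot)
}
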