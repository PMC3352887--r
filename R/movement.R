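#' Movement threshold in pixels from an FBL fraction
#'
#' Thresholds are specified as fractions of the fly body length so the same
#' sensitivity setting transfers across focal distances. The pixel threshold
#' is the fraction of the FBL rounded half-up, floored at 1 px: for a 10 px
#' fly the 20%, 50% and 100% settings give 2, 5 and 10 px, and the 150%
#' maximum cutoff gives 15 px.
#'
#' @param fbl_px Fly body length, pixels (> 0).
#' @param fraction FBL fraction (> 0), e.g. 0.5 for the 50% setting.
#' @return Threshold in whole pixels (>= 1).
#' @export
fbl_threshold <- function(fbl_px, fraction) {
  stopifnot(fbl_px > 0, fraction > 0)
  pmax(1, floor(fbl_px * fraction + 0.5))
}

#' Euclidean displacement between consecutive positions
#'
#' @param x1,y1,x2,y2 Pixel coordinates (vectorized).
#' @return Euclidean distance(s), pixels.
#' @export
displacement <- function(x1, y1, x2, y2) {
  sqrt((x2 - x1)^2 + (y2 - y1)^2)
}

#' Score per-second binary movement from a trajectory
#'
#' The displacement between each pair of consecutive 1 Hz records is compared
#' against a minimum and a maximum cutoff: a second scores 1 (move) when
#' `min_px <= d <= max_px` (the minimum is inclusive — the fly must move *at
#' least* that distance). Displacements above `max_px` are physically
#' unattainable in one second and are scored 0 with an `artifact` flag — they
#' indicate tracking error, not locomotion. The first second of a trajectory
#' and any second adjacent to an invalid record scores 0.
#'
#' @param traj Tibble of track records: `fly_id`, `t`, `x`, `y` and
#'   optionally `valid` (assumed `TRUE` when absent). Multiple flies are
#'   handled per group.
#' @param min_px Minimum movement threshold, pixels (see [fbl_threshold()]).
#' @param max_px Maximum plausible displacement, pixels; defaults to
#'   infinity (no artifact screening).
#' @return A tibble with one row per input record: `fly_id`, `t`, `moving`
#'   (0/1 integer) and `artifact` (logical).
#' @export
classify_movement <- function(traj, min_px, max_px = Inf) {
  stopifnot(min_px > 0, min_px <= max_px)
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  if (!"valid" %in% names(traj)) traj$valid <- TRUE
  traj |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      d = displacement(dplyr::lag(.data$x), dplyr::lag(.data$y),
                       .data$x, .data$y),
      pair_ok = .data$valid & dplyr::lag(.data$valid, default = FALSE) &
        dplyr::coalesce(.data$t - dplyr::lag(.data$t), -1) == 1,
      moving = as.integer(.data$pair_ok & !is.na(.data$d) &
                            .data$d >= min_px & .data$d <= max_px),
      artifact = .data$pair_ok & !is.na(.data$d) & .data$d > max_px
    ) |>
    dplyr::ungroup() |>
    dplyr::select("fly_id", "t", valid = "valid", moving = "moving",
                  artifact = "artifact")
}

#' Bin a per-second activity series into DAM-like counts
#'
#' Sums the binary movement series into fixed-length bins aligned to ZT 0.
#' Only complete bins (all seconds present) are kept, matching how
#' beam-monitor analyses operate on whole bins. Minute bins containing any
#' second from a run of more than 60 s of invalid tracking are flagged
#' (`flagged = TRUE`) for QC; their counts are still reported.
#'
#' @param activity Tibble from [classify_movement()] (or any tibble with
#'   `fly_id`, `t`, `moving`, optionally `valid`).
#' @param schedule A [light_schedule()].
#' @param bin_length_s Bin length in seconds: 60 and 1800 mirror the 1-min
#'   and 30-min bins of standard DAM files.
#' @return A tibble: `fly_id`, `bin_start_min` (ZT-anchored experiment
#'   minute of the bin start), `day`, `period` (LP/DP of the bin start),
#'   `count`, `flagged`. Carries attribute `bin_length_s`.
#' @export
bin_counts <- function(activity, schedule, bin_length_s = 60) {
  stopifnot(bin_length_s > 0)
  if (!"valid" %in% names(activity)) activity$valid <- TRUE
  act <- activity |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      invalid_run = bad_run_length(!.data$valid) > 60,
      bin = (.data$t - schedule$lights_on_s) %/% bin_length_s
    ) |>
    dplyr::ungroup()
  check_entrained(act$t, schedule)
  out <- act |>
    dplyr::group_by(.data$fly_id, .data$bin) |>
    dplyr::summarise(
      count = sum(.data$moving),
      n_s = dplyr::n(),
      flagged = any(.data$invalid_run),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_s == bin_length_s) |>
    dplyr::mutate(
      bin_start_min = .data$bin * bin_length_s / 60,
      day = as.integer(.data$bin_start_min %/% schedule$cycle_min),
      period = period_of_zt(.data$bin_start_min %% schedule$cycle_min,
                            schedule)
    ) |>
    dplyr::select("fly_id", "bin_start_min", "day", "period", "count",
                  "flagged")
  attr(out, "bin_length_s") <- bin_length_s
  out
}

# Length of the run of TRUEs each element belongs to (0 for FALSE elements).
bad_run_length <- function(bad) {
  if (length(bad) == 0) return(integer(0))
  r <- rle(bad)
  rep(ifelse(r$values, r$lengths, 0L), r$lengths)
}

#' Emulate an infrared beam from coordinate data
#'
#' A virtual beam is a line placed at the physical beam's tube-axis
#' coordinate. A second scores one activity event when the fly's axis
#' positions at the previous and current ticks lie strictly on opposite
#' sides of the beam, or when the fly lands exactly on the beam coming from
#' off-beam; consecutive on-beam samples count once (a fly resting on the
#' beam is not re-counted). Events need two consecutive valid records.
#'
#' @param traj Track-record tibble (`fly_id`, `t`, `x`, `y`, optional
#'   `valid`).
#' @param cal A [calibration()]; supplies the axis projection and default
#'   beam position.
#' @param beam_x Beam position on the tube axis, pixels (default
#'   `cal$beam_x`).
#' @return A tibble `fly_id`, `t`, `moving` (0/1 crossing events), `valid` —
#'   the same shape as [classify_movement()] output so it feeds
#'   [bin_counts()] directly.
#' @export
virtual_beam <- function(traj, cal, beam_x = cal$beam_x) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  if (beam_x < cal$axis_min || beam_x > cal$axis_max) {
    stop("beam_x outside the ROI tube axis", call. = FALSE)
  }
  if (!"valid" %in% names(traj)) traj$valid <- TRUE
  traj |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      p = axis_position(.data$x, .data$y, cal) - beam_x,
      p0 = dplyr::lag(.data$p),
      pair_ok = .data$valid & dplyr::lag(.data$valid, default = FALSE) &
        dplyr::coalesce(.data$t - dplyr::lag(.data$t), -1) == 1,
      moving = as.integer(.data$pair_ok & !is.na(.data$p0) &
                            (.data$p0 * .data$p < 0 |
                               (.data$p == 0 & .data$p0 != 0)))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("fly_id", "t", moving = "moving", valid = "valid")
}
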