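#' Per-minute immobility from 1-minute activity counts
#'
#' A minute is immobile when its activity count is zero — the input to the
#' field-standard 5-minute sleep rule.
#'
#' @param counts 1-minute binned counts from [bin_counts()] (or a DAM file
#'   read with [read_dam()]); must carry `bin_length_s = 60`.
#' @return Tibble `fly_id`, `minute` (ZT-anchored experiment minute), `day`,
#'   `period`, `immobile` (0/1).
#' @export
immobile_minutes <- function(counts) {
  bl <- attr(counts, "bin_length_s")
  if (!is.null(bl) && bl != 60) {
    stop("sleep scoring requires 1-minute bins (got ", bl, " s)",
         call. = FALSE)
  }
  counts |>
    dplyr::transmute(.data$fly_id, minute = as.integer(.data$bin_start_min),
                     .data$day, .data$period,
                     immobile = as.integer(.data$count == 0))
}

#' Find sleep bouts by the 5-minute immobility rule
#'
#' A sleep bout (episode) is a maximal run of consecutive immobile minutes of
#' length at least `min_bout` (default 5, the field-standard operational
#' definition of fly sleep); shorter immobile runs are wake. Runs must be
#' contiguous in time — a gap in the minute grid breaks a run.
#'
#' @param immobility Tibble from [immobile_minutes()].
#' @param schedule A [light_schedule()].
#' @param min_bout Minimum bout duration, minutes.
#' @return Tibble of bouts: `fly_id`, `onset_min`, `duration_min`, `day` and
#'   `period` of onset.
#' @export
find_sleep_bouts <- function(immobility, schedule, min_bout = 5) {
  stopifnot(min_bout >= 1)
  immobility |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$minute, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      gap <- c(TRUE, diff(df$minute) != 1)
      block <- cumsum(gap)
      purrr::map_dfr(split(df, block), function(b) {
        r <- rle(b$immobile == 1)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        keep <- r$values & r$lengths >= min_bout
        tibble::tibble(onset_min = b$minute[starts[keep]],
                       duration_min = r$lengths[keep])
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      day = as.integer(.data$onset_min %/% schedule$cycle_min),
      period = period_of_zt(.data$onset_min %% schedule$cycle_min, schedule)
    )
}

# Minutes covered by any bout, as a logical vector aligned to `minutes`.
minutes_in_bouts <- function(minutes, bouts) {
  asleep <- rep(FALSE, length(minutes))
  if (nrow(bouts) > 0) {
    for (i in seq_len(nrow(bouts))) {
      asleep <- asleep | (minutes >= bouts$onset_min[i] &
                            minutes < bouts$onset_min[i] + bouts$duration_min[i])
    }
  }
  asleep
}

#' Sleep-architecture metrics per fly, day and analysis period
#'
#' Computes the standard sleep panel for each complete day and each analysis
#' period (FULL24, light period LP, dark period DP):
#' * `total_sleep_min` — minutes inside sleep bouts that fall in the period
#'   (a bout spanning the LP/DP boundary contributes its minutes to each
#'   period, so LP + DP totals add up to the 24 h total);
#' * `episode_count`, `mean_episode_min`, `max_episode_min` — over bouts
#'   whose *onset* lies in the period;
#' * `latency_min` — minutes from the period's lights transition to the
#'   first bout onset in the period, capped at the period length when no
#'   sleep occurs (`latency_capped` flags the cap); `NA` for FULL24, which
#'   has no anchoring transition;
#' * `mean_wake_min` — mean length of maximal wake runs with onset in the
#'   period;
#' * `activity_while_active` — activity counts per waking minute
#'   (locomotor intensity decoupled from sleep amount); `NA` if the period
#'   has no waking minutes.
#'
#' Incomplete days (fewer than `cycle_min` minute bins) are dropped.
#'
#' @param counts 1-minute counts from [bin_counts()].
#' @param schedule A [light_schedule()].
#' @param min_bout Minimum sleep-bout duration, minutes (default 5).
#' @return Tidy tibble: one row per fly x day x period.
#' @export
sleep_metrics <- function(counts, schedule, min_bout = 5) {
  imm <- immobile_minutes(counts)
  cyc <- schedule$cycle_min
  imm |>
    dplyr::left_join(
      dplyr::select(counts, "fly_id", minute = "bin_start_min", "count"),
      by = c("fly_id", "minute")
    ) |>
    dplyr::group_by(.data$fly_id, .data$day) |>
    dplyr::filter(dplyr::n() == cyc) |>
    dplyr::group_modify(~ day_metrics(.x, schedule, min_bout)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$fly_id, .data$day,
                   match(.data$period, PERIODS))
}

day_metrics <- function(df, schedule, min_bout) {
  df <- dplyr::arrange(df, .data$minute)
  bouts <- find_sleep_bouts(
    dplyr::mutate(df, fly_id = "f"), schedule, min_bout
  )
  asleep <- minutes_in_bouts(df$minute, bouts)
  zt <- df$minute %% schedule$cycle_min
  min_period <- period_of_zt(zt, schedule)
  # wake runs over the day, attributed to the period of their onset
  wr <- rle(!asleep)
  w_ends <- cumsum(wr$lengths)
  w_starts <- w_ends - wr$lengths + 1
  wake_runs <- tibble::tibble(
    len = wr$lengths[wr$values],
    onset_period = min_period[w_starts[wr$values]]
  )
  purrr::map_dfr(PERIODS, function(p) {
    in_p <- if (p == "FULL24") rep(TRUE, nrow(df)) else min_period == p
    b <- if (p == "FULL24") bouts else bouts[bouts$period == p, ]
    waking <- in_p & !asleep
    n_wake <- sum(waking)
    lat <- NA_real_
    lat_capped <- NA
    if (p %in% c("LP", "DP")) {
      anchor <- if (p == "LP") 0 else schedule$photoperiod_min
      lat <- if (nrow(b) > 0) {
        min(b$onset_min %% schedule$cycle_min) - anchor
      } else {
        period_length_min(p, schedule)
      }
      lat_capped <- nrow(b) == 0
    }
    wl <- wake_runs$len[if (p == "FULL24") rep(TRUE, nrow(wake_runs))
                        else wake_runs$onset_period == p]
    tibble::tibble(
      period = p,
      total_sleep_min = sum(asleep & in_p),
      episode_count = nrow(b),
      mean_episode_min = if (nrow(b) > 0) mean(b$duration_min) else 0,
      max_episode_min = if (nrow(b) > 0) max(b$duration_min) else 0,
      latency_min = lat,
      latency_capped = lat_capped,
      mean_wake_min = if (length(wl) > 0) mean(wl) else 0,
      activity_while_active =
        if (n_wake > 0) sum(df$count[waking]) / n_wake else NA_real_
    )
  })
}

#' Sleep latency for a light or dark period
#'
#' Minutes from the period's lights transition (lights-on for LP, lights-off
#' for DP) to the onset of the first sleep bout starting in that period on
#' that day; the period length when no bout starts in it.
#'
#' @param bouts Bout tibble from [find_sleep_bouts()].
#' @param schedule A [light_schedule()].
#' @param period `"LP"` or `"DP"` (`"FULL24"` is rejected: latency is
#'   anchored to a lights transition).
#' @param day Analysis day index (default 0).
#' @return Latency in minutes.
#' @export
sleep_latency <- function(bouts, schedule, period, day = 0) {
  if (!period %in% c("LP", "DP")) {
    stop("latency is defined relative to a lights transition; ",
         "use period 'LP' or 'DP'", call. = FALSE)
  }
  anchor <- if (period == "LP") 0 else schedule$photoperiod_min
  b <- bouts[bouts$period == period & bouts$day == day, ]
  if (nrow(b) == 0) return(period_length_min(period, schedule))
  min(b$onset_min %% schedule$cycle_min) - anchor
}

#' Average per-day metrics within flies, then summarise across flies
#'
#' Experimental days are averaged together per fly first; group statistics
#' (mean, SD, SEM) are then computed over the per-fly means, so flies — not
#' fly-days — are the unit of replication.
#'
#' @param metrics Tidy metric tibble from [sleep_metrics()] (or any tibble
#'   with `fly_id`, `day`, `period` and numeric metric columns).
#' @return An object of class `sleep_summary` with components `per_fly`
#'   (fly x period means over days) and `group` (period x metric mean, sd,
#'   sem, n). Use [generics::tidy()] / [generics::glance()] or the
#'   components directly.
#' @export
average_across_days <- function(metrics) {
  if (nrow(metrics) == 0) stop("no complete days to average", call. = FALSE)
  num_cols <- setdiff(
    names(metrics)[vapply(metrics, is.numeric, logical(1))],
    c("day")
  )
  per_fly <- metrics |>
    dplyr::group_by(.data$fly_id, .data$period) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  group <- per_fly |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "metric") |>
    dplyr::group_by(.data$period, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      sem = .data$sd / sqrt(.data$n),
      .groups = "drop"
    )
  structure(list(per_fly = per_fly, group = group), class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("<sleep_summary> %d flies, %d periods\n",
              dplyr::n_distinct(x$per_fly$fly_id),
              dplyr::n_distinct(x$per_fly$period)))
  print(x$group)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sleep summary: group means with SEM
#'
#' @param x A `sleep_summary` from [average_across_days()].
#' @param ... Unused.
#' @return Tibble `period`, `metric`, `mean`, `sd`, `sem`, `n`.
#' @export
tidy.sleep_summary <- function(x, ...) x$group

#' One-row overview of a sleep summary
#'
#' @param x A `sleep_summary`.
#' @param ... Unused.
#' @return Tibble with fly count and mean days per fly.
#' @export
glance.sleep_summary <- function(x, ...) {
  tibble::tibble(
    n_flies = dplyr::n_distinct(x$per_fly$fly_id),
    mean_days = mean(x$per_fly$n_days)
  )
}

#' Sleep timecourse in 30-minute ZT bins
#'
#' Minutes of sleep (membership in a >= `min_bout`-minute immobility bout)
#' per ZT-aligned 30-minute bin, per fly and day — the standard sleep
#' profile line plot. Values range 0–30.
#'
#' @param counts 1-minute counts from [bin_counts()].
#' @param schedule A [light_schedule()].
#' @param min_bout Minimum bout duration, minutes.
#' @param bin_min Profile bin width, minutes (default 30).
#' @return Tibble `fly_id`, `day`, `zt_bin_min` (bin start, ZT minutes),
#'   `sleep_min`. Incomplete days are dropped.
#' @export
sleep_timecourse <- function(counts, schedule, min_bout = 5, bin_min = 30) {
  imm <- immobile_minutes(counts)
  cyc <- schedule$cycle_min
  imm |>
    dplyr::group_by(.data$fly_id, .data$day) |>
    dplyr::filter(dplyr::n() == cyc) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$minute)
      bouts <- find_sleep_bouts(dplyr::mutate(df, fly_id = "f"),
                                schedule, min_bout)
      asleep <- minutes_in_bouts(df$minute, bouts)
      tibble::tibble(
        zt_bin_min = (df$minute %% cyc) %/% bin_min * bin_min,
        asleep = asleep
      ) |>
        dplyr::group_by(.data$zt_bin_min) |>
        dplyr::summarise(sleep_min = sum(.data$asleep), .groups = "drop")
    }) |>
    dplyr::ungroup()
}
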