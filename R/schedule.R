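#' Define a light:dark schedule
#'
#' All analyses are anchored to Zeitgeber time (ZT): ZT 0 is lights-on.
#' Light intervals are half-open `[lights-on, lights-off)`, so the minute at
#' ZT 0 is light and the minute at `photoperiod_min` (ZT 12 in a 12:12 cycle)
#' is the first dark minute.
#'
#' @param lights_on_s Experiment time, in seconds since recording start, of
#'   the first lights-on (ZT 0). Data before this instant are treated as an
#'   unentrained prefix and rejected by ZT arithmetic.
#' @param photoperiod_min Length of the light phase in minutes (default 720,
#'   i.e. 12 h).
#' @param cycle_min Length of the full cycle in minutes (default 1440).
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule()
#' zt_minute(725 * 60, sched)
#' @export
light_schedule <- function(lights_on_s = 0, photoperiod_min = 720,
                           cycle_min = 1440) {
  stopifnot(length(lights_on_s) == 1, lights_on_s >= 0,
            photoperiod_min > 0, photoperiod_min < cycle_min)
  structure(
    list(lights_on_s = as.numeric(lights_on_s),
         photoperiod_min = as.numeric(photoperiod_min),
         cycle_min = as.numeric(cycle_min)),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> ZT0 at t = %gs, %g:%g LD (min)\n",
              x$lights_on_s, x$photoperiod_min,
              x$cycle_min - x$photoperiod_min))
  invisible(x)
}

check_entrained <- function(t, schedule) {
  if (any(t < schedule$lights_on_s)) {
    stop("time(s) before the first lights-on (unentrained prefix); ",
         "ZT is undefined there", call. = FALSE)
  }
}

#' Zeitgeber minute of an experiment time
#'
#' Minutes elapsed since the most recent lights-on, modulo the cycle length.
#'
#' @param t Experiment time(s) in seconds. Must be at or after the first
#'   lights-on.
#' @param schedule A [light_schedule()].
#' @return Integer-valued ZT minute(s) in `[0, cycle_min)`.
#' @export
zt_minute <- function(t, schedule) {
  check_entrained(t, schedule)
  ((t - schedule$lights_on_s) %/% 60) %% schedule$cycle_min
}

#' Is an experiment time in the light phase?
#'
#' @inheritParams zt_minute
#' @return Logical vector, `TRUE` during the light phase (half-open
#'   convention: ZT 0 is light, the lights-off minute is dark).
#' @export
in_light <- function(t, schedule) {
  zt_minute(t, schedule) < schedule$photoperiod_min
}

# Analysis periods: the full day and its light/dark halves.
PERIODS <- c("FULL24", "LP", "DP")

# Period label of a ZT minute (vectorized); FULL24 never returned.
period_of_zt <- function(zt_min, schedule) {
  ifelse(zt_min < schedule$photoperiod_min, "LP", "DP")
}

# Length of an analysis period in minutes.
period_length_min <- function(period, schedule) {
  switch(period,
    FULL24 = schedule$cycle_min,
    LP = schedule$photoperiod_min,
    DP = schedule$cycle_min - schedule$photoperiod_min,
    stop("unknown period: ", period)
  )
}

# ZT-anchored experiment minute index (0 = the minute starting at ZT0 of the
# first analysis day). All binning in the package aligns to this grid.
exp_minute <- function(t, schedule) {
  check_entrained(t, schedule)
  (t - schedule$lights_on_s) %/% 60
}
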