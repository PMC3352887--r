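# Shared fixtures: everything is built in code at test time.

# A 1 Hz trajectory from axis positions (y transverse, constant by default).
make_traj <- function(x, y = 20, t = seq_along(x) - 1, fly_id = "f1",
                      valid = TRUE) {
  tibble::tibble(fly_id = fly_id, t = t, x = as.numeric(x),
                 y = rep_len(as.numeric(y), length(x)),
                 valid = rep_len(valid, length(x)))
}

# Default tube: 260 px axis, 65 mm, food at the high end, beam mid-tube.
test_cal <- function(...) {
  calibration(c(xmin = 0, xmax = 260, ymin = 0, ymax = 40), fbl_px = 10, ...)
}

test_sched <- function() light_schedule()

# Minute-count tibble shaped like bin_counts() output from a count vector.
make_counts <- function(counts, fly_id = "f1", start_min = 0,
                        schedule = test_sched()) {
  mins <- start_min + seq_along(counts) - 1
  out <- tibble::tibble(
    fly_id = fly_id, bin_start_min = as.numeric(mins),
    day = as.integer(mins %/% schedule$cycle_min),
    period = ifelse(mins %% schedule$cycle_min < schedule$photoperiod_min,
                    "LP", "DP"),
    count = as.integer(counts), flagged = FALSE
  )
  attr(out, "bin_length_s") <- 60
  out
}

# Per-minute sleep membership by direct run-length enumeration.
minutes_asleep_oracle <- function(v, min_bout = 5) {
  r <- rle(v == 0)
  rep(r$values & r$lengths >= min_bout, r$lengths)
}

# A full-day minute-count vector with sleep bouts at given onsets/durations
# (active minutes get count 1 elsewhere).
day_counts_with_bouts <- function(bouts_onset, bouts_dur, fill = 1L) {
  v <- rep(fill, 1440)
  for (i in seq_along(bouts_onset)) {
    v[bouts_onset[i] + seq_len(bouts_dur[i])] <- 0L
  }
  v
}
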