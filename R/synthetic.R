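#' Parameters for the synthetic fly simulator
#'
#' The simulator emulates a single fly confined to a 65 mm tube, alternating
#' rest and active bouts whose exponential mean durations follow a 24 h
#' square wave (light vs dark phase). Active motion is a reflected,
#' food-biased random walk along the tube axis; rest is stationary with
#' small Gaussian positional jitter. Defaults describe a wild-type-like fly:
#' equal 10 min rest/active bouts in the light (50% rest, a siesta-bearing
#' but active day) and 25 min rest vs 5 min active bouts in the dark (~83%
#' rest, consolidated night sleep), with rest jitter far below the 2 px
#' movement threshold of a 10 px fly at the 20% FBL setting so that true
#' rest scores as immobility. The default geometry is self-consistent with
#' a 10 px body length: a 2.5 mm fly at 10 px is ~4 px/mm, so the 65 mm
#' tube spans 260 px and a walking fly at ~2 mm/s steps ~8 px/s — above the
#' 5 px minimum threshold at 50% FBL and almost always below the 15 px
#' (150% FBL) artifact cutoff.
#'
#' @param seed Integer seed; the simulation draws from a single seeded
#'   stream and is fully reproducible.
#' @param days Number of simulated 24 h days.
#' @param tube_px Tube axis length, pixels.
#' @param tube_width_px Tube transverse width, pixels.
#' @param margin_px Blank border around the ROI in rendered frames.
#' @param fbl_px Fly body length, pixels (rendered ellipse major axis).
#' @param rest_mean_min,active_mean_min Named numeric vectors
#'   `c(light = , dark = )`: mean bout durations in minutes by phase.
#' @param speed_mean,speed_sd Per-second step magnitude during active bouts
#'   is `|N(speed_mean, speed_sd)|` px/s.
#' @param food_bias Probability that an active step heads toward the food
#'   end; 0.5 is unbiased.
#' @param rest_jitter_sd SD of per-second positional jitter at rest, px.
#' @param fly_intensity,background 8-bit intensities of the rendered fly and
#'   background (arbitrary fixture constants giving contrast well above the
#'   default detection threshold).
#' @param food_end Which axis end holds the food (`"high"` or `"low"`).
#' @return An object of class `sim_params`, including the derived
#'   [calibration()] (`$cal`) and [light_schedule()] (`$schedule`).
#' @export
sim_params <- function(seed = 1, days = 1, tube_px = 260,
                       tube_width_px = 40, margin_px = 10, fbl_px = 10,
                       rest_mean_min = c(light = 10, dark = 25),
                       active_mean_min = c(light = 10, dark = 5),
                       speed_mean = 8, speed_sd = 2, food_bias = 0.6,
                       rest_jitter_sd = 0.3,
                       fly_intensity = 40, background = 220,
                       food_end = "high") {
  stopifnot(days > 0, tube_px > 4 * fbl_px, tube_width_px > fbl_px,
            all(rest_mean_min > 0), all(active_mean_min > 0),
            speed_mean > 0, speed_sd >= 0, food_bias >= 0, food_bias <= 1,
            rest_jitter_sd >= 0)
  roi <- c(xmin = margin_px, xmax = margin_px + tube_px,
           ymin = margin_px, ymax = margin_px + tube_width_px)
  cal <- calibration(roi, fbl_px = fbl_px, food_end = food_end)
  structure(
    list(seed = as.integer(seed), days = days, tube_px = tube_px,
         tube_width_px = tube_width_px, margin_px = margin_px,
         fbl_px = fbl_px, rest_mean_min = rest_mean_min,
         active_mean_min = active_mean_min, speed_mean = speed_mean,
         speed_sd = speed_sd, food_bias = food_bias,
         rest_jitter_sd = rest_jitter_sd, fly_intensity = fly_intensity,
         background = background, food_end = food_end,
         frame_dim = c(tube_width_px + 2 * margin_px,
                       tube_px + 2 * margin_px),
         cal = cal, schedule = light_schedule(0)),
    class = "sim_params"
  )
}

#' Expected rest fraction by phase
#'
#' Under alternating exponential bouts the long-run rest fraction in a phase
#' is `rest_mean / (rest_mean + active_mean)` — the analytic expectation the
#' simulator's realized rest time is checked against.
#'
#' @param params A [sim_params()].
#' @return Named vector `c(light = , dark = )`.
#' @export
expected_rest_fraction <- function(params) {
  params$rest_mean_min / (params$rest_mean_min + params$active_mean_min)
}

#' Simulate a circadian two-state fly trajectory
#'
#' Draws alternating rest/active bouts (exponential durations, phase-
#' dependent means drawn at bout onset), walks the fly along the tube axis
#' during active bouts (reflected at the tube ends, biased toward food) and
#' jitters it in place during rest. Positions are frame pixel coordinates
#' inside the ROI, sampled at 1 Hz; the fly centre stays one body length
#' clear of the tube ends so rendered flies remain inside the ROI.
#'
#' @param params A [sim_params()].
#' @param fly_id Identifier for the simulated fly.
#' @return A list of class `fly_sim`:
#'   * `trajectory` — tibble `fly_id`, `t`, `x`, `y`, `valid` (all `TRUE`);
#'   * `truth` — tibble `t`, `state` (`"rest"`/`"active"`), `x`, `y`;
#'   * `params`, `cal`, `schedule`.
#' @export
simulate_trajectory <- function(params, fly_id = "sim1") {
  set.seed(params$seed)
  n <- as.integer(round(params$days * 86400))
  sched <- params$schedule
  ph_light <- function(t) ((t / 60) %% sched$cycle_min) < sched$photoperiod_min

  # draw the alternating bout sequence
  states <- character(0); durs <- integer(0)
  t_cur <- 0
  state <- if (runif(1) < expected_rest_fraction(params)[
    if (ph_light(0)) "light" else "dark"]) "rest" else "active"
  while (t_cur < n) {
    phase <- if (ph_light(t_cur)) "light" else "dark"
    mean_s <- 60 * (if (state == "rest") params$rest_mean_min[phase]
                    else params$active_mean_min[phase])
    dur <- max(1L, as.integer(round(rexp(1, 1 / mean_s))))
    dur <- min(dur, n - t_cur)
    states <- c(states, state); durs <- c(durs, dur)
    t_cur <- t_cur + dur
    state <- if (state == "rest") "active" else "rest"
  }

  cal <- params$cal
  lo <- cal$axis_min + params$fbl_px
  hi <- cal$axis_max - params$fbl_px
  ylo <- cal$roi$ymin + params$fbl_px / 2 + 1
  yhi <- cal$roi$ymax - params$fbl_px / 2 - 1
  dir_food <- if (params$food_end == "high") 1 else -1

  x <- numeric(n); y <- numeric(n); st <- character(n)
  cx <- runif(1, lo, hi)
  cy <- runif(1, ylo, yhi)
  pos <- 0L
  for (b in seq_along(durs)) {
    len <- durs[b]
    idx <- pos + seq_len(len)
    if (states[b] == "rest") {
      x[idx] <- pmin(hi, pmax(lo, cx + rnorm(len, 0, params$rest_jitter_sd)))
      y[idx] <- pmin(yhi, pmax(ylo, cy + rnorm(len, 0, params$rest_jitter_sd)))
    } else {
      mags <- abs(rnorm(len, params$speed_mean, params$speed_sd))
      dirs <- ifelse(runif(len) < params$food_bias, dir_food, -dir_food)
      ysteps <- rnorm(len, 0, 1)
      px <- cx; py <- cy
      for (i in seq_len(len)) {
        px <- px + dirs[i] * mags[i]
        if (px > hi) px <- 2 * hi - px
        if (px < lo) px <- 2 * lo - px
        px <- min(hi, max(lo, px))
        py <- min(yhi, max(ylo, py + ysteps[i]))
        x[idx[i]] <- px
        y[idx[i]] <- py
      }
      cx <- x[idx[len]]; cy <- y[idx[len]]
    }
    st[idx] <- states[b]
    pos <- pos + len
  }

  truth <- tibble::tibble(t = seq_len(n) - 1L, state = st, x = x, y = y)
  structure(
    list(
      trajectory = tibble::tibble(fly_id = fly_id, t = truth$t,
                                  x = x, y = y, valid = TRUE),
      truth = truth,
      params = params, cal = cal, schedule = sched
    ),
    class = "fly_sim"
  )
}

#' @export
print.fly_sim <- function(x, ...) {
  cat(sprintf("<fly_sim> %d s (%g d), seed %d, rest fraction %.2f\n",
              nrow(x$truth), x$params$days, x$params$seed,
              mean(x$truth$state == "rest")))
  invisible(x)
}

#' Ground-truth beam crossings from true positions
#'
#' Sign-change crossings of the beam computed directly from the simulator's
#' true positions — the oracle a coordinate-level virtual beam is checked
#' against.
#'
#' @param sim A `fly_sim` from [simulate_trajectory()].
#' @param beam_x Beam axis position (default: the calibration's).
#' @return Tibble `t`, `event` (0/1) covering every simulated second.
#' @export
ground_truth_beam <- function(sim, beam_x = sim$cal$beam_x) {
  p <- axis_position(sim$truth$x, sim$truth$y, sim$cal) - beam_x
  p0 <- dplyr::lag(p)
  ev <- as.integer(!is.na(p0) & (p0 * p < 0 | (p == 0 & p0 != 0)))
  tibble::tibble(t = sim$truth$t, event = ev)
}

#' Ground-truth sleep bouts from true behavioral state
#'
#' A minute is truly immobile when all of its 60 seconds are in the rest
#' state; maximal runs of at least `min_bout` such minutes are ground-truth
#' sleep bouts, the reference for parameter-recovery checks of the scored
#' sleep pipeline.
#'
#' @param sim A `fly_sim`.
#' @param min_bout Minimum bout duration, minutes.
#' @return Tibble `onset_min`, `duration_min`.
#' @export
ground_truth_rest_bouts <- function(sim, min_bout = 5) {
  minute <- sim$truth$t %/% 60
  full <- tapply(sim$truth$state == "rest", minute, all)
  r <- rle(as.vector(full))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_bout
  tibble::tibble(
    onset_min = as.integer(names(full))[starts[keep]],
    duration_min = r$lengths[keep]
  )
}

#' Render synthetic frames from true positions
#'
#' Produces the imaging model the tracker expects: a light background with a
#' dark filled ellipse (major axis along the tube, length `fbl_px`; minor
#' axis half that) at each true position, plus a fly-free reference frame.
#' Optional additive Gaussian noise; intensities clamped to `[0, 255]`.
#'
#' @param positions Tibble with `x`, `y` frame coordinates (e.g. rows of a
#'   `fly_sim` truth); one frame is rendered per row.
#' @param params A [sim_params()] supplying geometry and intensities.
#' @param noise_sd SD of additive Gaussian pixel noise (applied to frames,
#'   not to the reference).
#' @return List with `frames` (list of matrices) and `reference` (matrix).
#' @export
render_frames <- function(positions, params, noise_sd = 0) {
  d <- params$frame_dim
  if (any(positions$x < 0 | positions$x > d[2] - 1 |
          positions$y < 0 | positions$y > d[1] - 1)) {
    stop("position outside the frame", call. = FALSE)
  }
  reference <- matrix(params$background, nrow = d[1], ncol = d[2])
  a <- params$fbl_px / 2
  b <- params$fbl_px / 4
  frames <- purrr::map(seq_len(nrow(positions)), function(i) {
    f <- reference
    f <- draw_ellipse(f, positions$x[i], positions$y[i], a, b,
                      params$fly_intensity)
    if (noise_sd > 0) {
      f <- f + matrix(rnorm(length(f), 0, noise_sd), nrow = d[1])
      f[f < 0] <- 0
      f[f > 255] <- 255
    }
    f
  })
  list(frames = frames, reference = reference)
}

# Fill an axis-aligned ellipse (half-axes a >= b, a along x) into frame `f`.
draw_ellipse <- function(f, x, y, a, b, value) {
  cols <- max(1, floor(x - a) + 1):min(ncol(f), ceiling(x + a) + 1)
  rows <- max(1, floor(y - b) + 1):min(nrow(f), ceiling(y + b) + 1)
  cc <- outer(rep(1, length(rows)), cols - 1)
  rr <- outer(rows - 1, rep(1, length(cols)))
  inside <- ((cc - x) / a)^2 + ((rr - y) / b)^2 <= 1
  sub <- f[rows, cols, drop = FALSE]
  sub[inside] <- value
  f[rows, cols] <- sub
  f
}
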