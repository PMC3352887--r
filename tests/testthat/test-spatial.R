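cal650 <- function() {
  calibration(c(xmin = 0, xmax = 650, ymin = 0, ymax = 50), fbl_px = 10)
}

test_that("binned distance sums consecutive displacements in mm", {
  s <- test_sched()
  cal <- cal650()  # 0.1 mm/px
  still <- make_traj(rep(100, 120))
  d <- distance_series(still, cal, s)
  expect_true(all(d$distance_mm == 0))
  # constant 2 px/s along the axis: 60 steps in a full minute -> 12 mm
  # (the first minute has 59 steps: the first second has no predecessor)
  run <- make_traj(seq(100, by = 2, length.out = 121))
  d2 <- distance_series(run, cal, s)
  expect_equal(d2$distance_mm[d2$bin_start_min == 1], 12)
  expect_equal(d2$distance_mm[d2$bin_start_min == 0], 11.8)
  expect_error(distance_series(make_traj(numeric(0)), cal, s), "empty")
})

test_that("random-walk distance equals the stepwise-sum oracle", {
  set.seed(11)
  x <- cumsum(rnorm(180, 0, 3)) + 300
  y <- cumsum(rnorm(180, 0, 1)) + 25
  tr <- make_traj(x, y)
  d <- distance_series(tr, cal650(), test_sched())
  oracle <- sum(sqrt(diff(x[1:60])^2 + diff(y[1:60])^2)) * 0.1
  expect_equal(d$distance_mm[1], oracle, tolerance = 1e-10)
  expect_equal(nrow(d), 3)
  expect_equal(distance_per_day(d)$distance_mm, sum(d$distance_mm))
})

test_that("artifact steps contribute zero distance", {
  tr <- make_traj(c(100, 103, 200, 203, 206))  # one 97 px jump
  d <- distance_series(tr, cal650(), test_sched(), bin_s = 5, max_px = 15)
  expect_equal(d$distance_mm[1], 0.9)  # 3 + 3 + 3 px = 0.9 mm
})

test_that("decimated distance never exceeds the 1 Hz total", {
  cal <- cal650()
  # collinear constant-velocity path: equality at all strides
  line <- make_traj(seq(10, 130, by = 2))
  full <- subsample_distance(line, cal, 1)
  for (k in c(2, 3, 5)) {
    expect_equal(subsample_distance(line, cal, k), full, tolerance = 1e-10)
  }
  # stride 1 equals the distance_series total
  set.seed(12)
  tr <- make_traj(cumsum(rnorm(240, 0, 4)) + 300, 25)
  expect_equal(subsample_distance(tr, cal, 1),
               sum(distance_series(tr, cal, test_sched())$distance_mm),
               tolerance = 1e-10)
  # zigzag with 180 degree turns: stride 2 sees a shorter polyline
  zig <- make_traj(rep(c(100, 110), 10))
  expect_equal(subsample_distance(zig, cal, 1), 19 * 10 * 0.1)
  expect_equal(subsample_distance(zig, cal, 2), 0)  # returns to start
  expect_lt(subsample_distance(zig, cal, 2), subsample_distance(zig, cal, 1))
  expect_error(subsample_distance(zig, cal, 2.5), "integer")
})

test_that("subsampling inequality holds across random walks", {
  cal <- cal650()
  set.seed(13)
  for (rep in 1:20) {
    tr <- make_traj(pmin(650, pmax(0, cumsum(rnorm(120, 0, 5)) + 300)))
    full <- subsample_distance(tr, cal, 1)
    for (k in c(2, 5, 10)) {
      expect_lte(subsample_distance(tr, cal, k), full + 1e-12)
    }
  }
})

test_that("speed is distance over bin seconds, exactly", {
  d <- tibble::tibble(fly_id = "f1", bin_start_min = 0, day = 0L,
                      period = "LP", distance_mm = 12)
  sp <- speed_series(d, bin_s = 60)
  expect_equal(sp$speed_mm_s, 0.2)
  set.seed(14)
  tr <- make_traj(cumsum(rnorm(120, 0, 4)) + 300)
  ds <- distance_series(tr, cal650(), test_sched())
  sp2 <- speed_series(ds, 60)
  expect_equal(sp2$speed_mm_s * 60, sp2$distance_mm)
})

test_that("percent active counts flies with any movement in the bin", {
  s <- test_sched()
  mk_act <- function(id, moving) {
    tibble::tibble(fly_id = id, t = 0:59, moving = moving)
  }
  all_on <- dplyr::bind_rows(lapply(1:4, function(i) mk_act(paste0("f", i), 1L)))
  expect_equal(percent_active(all_on, s, bin_s = 60)$percent_active, 100)
  all_off <- dplyr::bind_rows(lapply(1:4, function(i) mk_act(paste0("f", i), 0L)))
  expect_equal(percent_active(all_off, s, bin_s = 60)$percent_active, 0)
  # 3 of 6 flies with a single moving second
  mixed <- dplyr::bind_rows(lapply(1:6, function(i) {
    mv <- rep(0L, 60); if (i <= 3) mv[10] <- 1L
    mk_act(paste0("f", i), mv)
  }))
  pa <- percent_active(mixed, s, bin_s = 60)
  expect_equal(pa$percent_active, 50)
  expect_equal(pa$n_flies, 6)
  expect_error(percent_active(all_on[0, ], s), "empty")
})

test_that("occupancy tallies valid seconds by section and bin", {
  s <- test_sched()
  cal <- test_cal()  # sections of 26 px, food high
  parked <- make_traj(rep(60, 60))  # section 3
  occ <- occupancy(parked, cal, s)
  expect_equal(occ$seconds[occ$section == 3], 60)
  expect_equal(sum(occ$seconds), 60)
  # random trajectory: per-second tally oracle + column sums
  set.seed(15)
  x <- runif(180, 0, 260)
  tr <- make_traj(x)
  occ2 <- occupancy(tr, cal, s)
  oracle <- table(factor(pmin(10, floor(x[1:60] / 26) + 1), levels = 1:10))
  first_bin <- occ2[occ2$bin_start_min == 0, ]
  expect_equal(first_bin$seconds[order(first_bin$section)],
               as.integer(oracle))
  sums <- tapply(occ2$seconds, occ2$bin_start_min, sum)
  expect_true(all(sums == 60))
  # invalid seconds are not tallied
  tr$valid[1:10] <- FALSE
  occ3 <- occupancy(tr, cal, s)
  expect_equal(sum(occ3$seconds[occ3$bin_start_min == 0]), 50)
})

test_that("sleep- and wake-conditioned occupancy partition the total", {
  s <- test_sched()
  cal <- test_cal()
  # 20 min parked in section 1 (sleeping), then 10 min moving near food
  x <- c(rep(10, 1200), runif(600, 200, 260))
  tr <- make_traj(x)
  act <- classify_movement(tr, 2)
  bouts <- find_sleep_bouts(immobile_minutes(bin_counts(act, s)), s)
  expect_gt(nrow(bouts), 0)
  tot <- occupancy(tr, cal, s)
  asl <- occupancy(tr, cal, s, state_filter = "asleep", bouts = bouts)
  awk <- occupancy(tr, cal, s, state_filter = "awake", bouts = bouts)
  # all three share one grid, so the partition holds cell-wise
  expect_equal(asl[, 1:3], tot[, 1:3])
  expect_equal(asl$seconds + awk$seconds, tot$seconds)
  expect_gt(sum(asl$seconds), 0)
  expect_gt(sum(awk$seconds), 0)
  expect_error(occupancy(tr, cal, s, state_filter = "asleep"), "bouts")
})

test_that("occupancy proportions normalise to one", {
  s <- test_sched()
  cal <- test_cal()
  occ <- occupancy(make_traj(rep(250, 120)), cal, s)
  pr <- occupancy_proportions(occ)
  expect_equal(pr$fraction[pr$section == 10], 1)
  expect_equal(sum(pr$fraction), 1, tolerance = 1e-9)
  set.seed(16)
  occ2 <- occupancy(make_traj(runif(600, 0, 260)), cal, s)
  pr2 <- occupancy_proportions(occ2)
  expect_equal(sum(pr2$fraction), 1, tolerance = 1e-9)
  expect_equal(pr2$fraction, pr2$seconds / sum(pr2$seconds))
  empty <- occ2[0, ]
  expect_error(occupancy_proportions(empty), "empty")
})
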