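test_that("immobile minutes are exactly the zero-count minutes", {
  cnt <- make_counts(c(0, 0, 3))
  expect_equal(immobile_minutes(cnt)$immobile, c(1L, 1L, 0L))
  allz <- make_counts(rep(0, 1440))
  expect_true(all(immobile_minutes(allz)$immobile == 1))
  set.seed(1)
  v <- rpois(500, 0.5)
  expect_equal(immobile_minutes(make_counts(v))$immobile,
               as.integer(v == 0))
  bad <- make_counts(c(0, 1))
  attr(bad, "bin_length_s") <- 1800
  expect_error(immobile_minutes(bad), "1-minute")
})

test_that("the 5-minute rule keeps runs of >= 5 immobile minutes", {
  s <- test_sched()
  five <- make_counts(c(1, rep(0, 5), 1, 1))
  b <- find_sleep_bouts(immobile_minutes(five), s)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 5)
  expect_equal(b$onset_min, 1)
  four <- make_counts(c(1, rep(0, 4), 1))
  expect_equal(nrow(find_sleep_bouts(immobile_minutes(four), s)), 0)
  # 10 immobile minutes broken at position 6: runs of 5 and 4 -> one bout
  split10 <- make_counts(c(1, rep(0, 5), 2, rep(0, 4), 1))
  b2 <- find_sleep_bouts(immobile_minutes(split10), s)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$duration_min, 5)
})

test_that("bouts are disjoint, >= 5 min, and match a run-length oracle", {
  s <- test_sched()
  set.seed(3)
  for (rep in 1:5) {
    v <- rbinom(1440, 1, 0.4)  # activity counts
    b <- find_sleep_bouts(immobile_minutes(make_counts(v)), s)
    r <- rle(v == 0)
    oracle_n <- sum(r$values & r$lengths >= 5)
    expect_equal(nrow(b), oracle_n)
    expect_true(all(b$duration_min >= 5))
    if (nrow(b) > 1) {
      expect_true(all(diff(b$onset_min) > head(b$duration_min, -1)))
    }
  }
})

test_that("a gap in the minute grid breaks an immobile run", {
  s <- test_sched()
  cnt <- dplyr::bind_rows(make_counts(rep(0, 3), start_min = 0),
                          make_counts(rep(0, 3), start_min = 10))
  attr(cnt, "bin_length_s") <- 60
  expect_equal(nrow(find_sleep_bouts(immobile_minutes(cnt), s)), 0)
})

test_that("sleep metrics handle the degenerate all-sleep and no-sleep days", {
  s <- test_sched()
  m <- sleep_metrics(make_counts(rep(0, 1440)), s)
  full <- m[m$period == "FULL24", ]
  expect_equal(full$total_sleep_min, 1440)
  expect_equal(full$episode_count, 1)
  expect_equal(full$mean_episode_min, 1440)
  expect_equal(full$max_episode_min, 1440)
  expect_true(is.na(full$activity_while_active))
  expect_equal(m$total_sleep_min[m$period == "LP"], 720)
  # never immobile >= 5 min: no sleep at all
  v <- rep(c(0, 0, 0, 0, 1), 288)
  m2 <- sleep_metrics(make_counts(v), s)
  expect_true(all(m2$total_sleep_min == 0))
  expect_true(all(m2$episode_count == 0))
  expect_equal(m2$latency_min[m2$period == "DP"], 720)
  expect_true(m2$latency_capped[m2$period == "DP"])
})

test_that("a crafted dark-period day reproduces hand-enumerated metrics", {
  # DP bouts of 120, 30 and 5 minutes at ZT 13:00, 18:00, 22:00
  v <- day_counts_with_bouts(c(780, 1080, 1320), c(120, 30, 5))
  m <- sleep_metrics(make_counts(v), test_sched())
  dp <- m[m$period == "DP", ]
  expect_equal(dp$total_sleep_min, 155)
  expect_equal(dp$episode_count, 3)
  expect_equal(dp$mean_episode_min, 155 / 3, tolerance = 1e-10)
  expect_equal(dp$max_episode_min, 120)
  expect_equal(dp$latency_min, 60)  # onset minute 780 - 720
  expect_equal(m$total_sleep_min[m$period == "LP"], 0)
  # waking DP minutes all carry count 1
  expect_equal(dp$activity_while_active, 1)
})

test_that("a bout spanning lights-off splits for totals, counts at onset", {
  # immobile ZT 11:50 to 12:10 (minutes 710..729): onset in LP
  v <- day_counts_with_bouts(710, 20)
  m <- sleep_metrics(make_counts(v), test_sched())
  expect_equal(m$total_sleep_min[m$period == "LP"], 10)
  expect_equal(m$total_sleep_min[m$period == "DP"], 10)
  expect_equal(m$total_sleep_min[m$period == "FULL24"], 20)
  expect_equal(m$episode_count[m$period == "LP"], 1)
  expect_equal(m$episode_count[m$period == "DP"], 0)
  # DP latency cap applies: no bout onset in DP
  expect_equal(m$latency_min[m$period == "DP"], 720)
})

test_that("sleep latency anchors at the lights transition", {
  s <- test_sched()
  v <- day_counts_with_bouts(c(100, 720, 1000), c(10, 6, 30))
  imm <- immobile_minutes(make_counts(v))
  bouts <- find_sleep_bouts(imm, s)
  expect_equal(sleep_latency(bouts, s, "DP"), 0)   # bout at the first dark minute
  expect_equal(sleep_latency(bouts, s, "LP"), 100)
  expect_error(sleep_latency(bouts, s, "FULL24"), "LP")
  # first DP bout at ZT 12:47 -> latency 47
  v2 <- day_counts_with_bouts(767, 20)
  b2 <- find_sleep_bouts(immobile_minutes(make_counts(v2)), s)
  expect_equal(sleep_latency(b2, s, "DP"), 47)
  # no sleep all night -> capped at period length
  b3 <- find_sleep_bouts(immobile_minutes(make_counts(rep(1, 1440))), s)
  expect_equal(sleep_latency(b3, s, "DP"), 720)
})

test_that("days average within flies before group summarising", {
  s <- test_sched()
  v1 <- day_counts_with_bouts(100, 400)
  v2 <- day_counts_with_bouts(100, 500)
  cnt <- dplyr::bind_rows(
    make_counts(c(v1, v2), fly_id = "a"),
    make_counts(c(v1, v1), fly_id = "b")
  )
  attr(cnt, "bin_length_s") <- 60
  m <- sleep_metrics(cnt, s)
  sm <- average_across_days(m)
  pf <- sm$per_fly
  expect_equal(pf$total_sleep_min[pf$fly_id == "a" & pf$period == "FULL24"],
               450)
  expect_equal(pf$total_sleep_min[pf$fly_id == "b" & pf$period == "FULL24"],
               400)
  g <- sm$group
  row <- g[g$period == "FULL24" & g$metric == "total_sleep_min", ]
  expect_equal(row$mean, 425)
  expect_equal(row$sem, sd(c(450, 400)) / sqrt(2))
  # identical days average to a single day
  same <- average_across_days(sleep_metrics(make_counts(c(v1, v1)), s))
  one <- sleep_metrics(make_counts(v1), s)
  expect_equal(
    same$per_fly$total_sleep_min[same$per_fly$period == "FULL24"],
    one$total_sleep_min[one$period == "FULL24"]
  )
  # random panel: two-stage mean oracle on one metric
  set.seed(4)
  days <- replicate(3, day_counts_with_bouts(sample(0:1000, 1), 200))
  mm <- sleep_metrics(make_counts(as.vector(days)), s)
  avg <- average_across_days(mm)
  expect_equal(
    avg$per_fly$total_sleep_min[avg$per_fly$period == "FULL24"],
    mean(mm$total_sleep_min[mm$period == "FULL24"])
  )
})

test_that("tidy/glance expose the group summary and panel size", {
  m <- sleep_metrics(make_counts(day_counts_with_bouts(100, 300)),
                     test_sched())
  sm <- average_across_days(m)
  td <- generics::tidy(sm)
  expect_true(all(c("period", "metric", "mean", "sem") %in% names(td)))
  gl <- generics::glance(sm)
  expect_equal(gl$n_flies, 1)
  expect_equal(gl$mean_days, 1)
})

test_that("sleep + wake partition every period exactly", {
  s <- test_sched()
  set.seed(5)
  for (rep in 1:5) {
    v <- rbinom(1440, 1, runif(1, 0.2, 0.8))
    m <- sleep_metrics(make_counts(v), s)
    for (p in c("FULL24", "LP", "DP")) {
      row <- m[m$period == p, ]
      plen <- if (p == "FULL24") 1440 else 720
      wake_min <- plen - row$total_sleep_min
      # activity_while_active uses exactly the wake minutes
      if (wake_min > 0) {
        expect_equal(row$activity_while_active * wake_min,
                     sum(v[(if (p == "LP") 1:720
                            else if (p == "DP") 721:1440
                            else 1:1440)] *
                           (1 - minutes_asleep_oracle(v)[
                             if (p == "LP") 1:720
                             else if (p == "DP") 721:1440 else 1:1440])))
      }
    }
    expect_equal(m$total_sleep_min[m$period == "LP"] +
                   m$total_sleep_min[m$period == "DP"],
                 m$total_sleep_min[m$period == "FULL24"])
  }
})

test_that("the sleep timecourse counts bout minutes per 30-min ZT bin", {
  s <- test_sched()
  tc_all <- sleep_timecourse(make_counts(rep(0, 1440)), s)
  expect_equal(nrow(tc_all), 48)
  expect_true(all(tc_all$sleep_min == 30))
  tc_none <- sleep_timecourse(make_counts(rep(1, 1440)), s)
  expect_true(all(tc_none$sleep_min == 0))
  # crafted: a 45-min bout over minutes 59..103 spans three bins (1, 30, 14)
  v <- day_counts_with_bouts(59, 45)
  tc <- sleep_timecourse(make_counts(v), s)
  expect_equal(tc$sleep_min[tc$zt_bin_min == 30], 1)
  expect_equal(tc$sleep_min[tc$zt_bin_min == 60], 30)
  expect_equal(tc$sleep_min[tc$zt_bin_min == 90], 14)
  expect_equal(sum(tc$sleep_min), 45)
})
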