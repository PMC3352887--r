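# flytrackr

Video tracking and sleep/locomotor analysis for *Drosophila* tube assays.

## The problem

The standard instrument for long-term fly sleep and circadian work is the
Drosophila Activity Monitor (DAM): each fly lives in a 65 × 5 × 5 mm glass
tube bisected by a single infrared beam, and every beam interruption is
tallied into 1- or 30-minute bins. Beam counts are cheap and robust but
spatially blind — a fly can walk, feed and groom for hours without crossing
the mid-tube beam, so beam-based scoring systematically overestimates sleep
and says nothing about *where* the fly is.

`flytrackr` implements the video alternative and the complete coordinate
analysis stack on top of it, for labs that record tubes with a camera and
want DAM-comparable sleep metrics plus position-resolved analyses:

* **Tracking** — a static reference image of the empty arena is subtracted
  from each frame; above-threshold pixels inside each tube's region of
  interest (ROI) are grouped into 8-connected components, size-filtered, and
  the largest component's centroid is recorded at 1 Hz as a sub-pixel
  (x, y) coordinate.
* **Movement scoring** — the per-second Euclidean displacement `d_t =
  ‖p_t − p_{t−1}‖` is binarised with thresholds expressed as fractions of
  the **fly body length (FBL)** so settings transfer across camera setups:
  a second scores movement when `min_px ≤ d_t ≤ max_px`, with
  `min_px = round(FBL × fraction)` (20%, 50% or 100%) and
  `max_px = round(FBL × 1.5)` screening physically unattainable jumps as
  tracking artifacts. For a 10 px fly these are 2, 5, 10 and 15 px.
* **Virtual beam** — a software line at the physical beam's coordinate;
  a strict sign change of `p_t − beam` between consecutive seconds emits one
  DAM-equivalent activity event, allowing a three-way comparison (DAM file,
  virtual beam, threshold scoring) on identical animals.
* **Sleep architecture** — the field-standard rule: a sleep bout is a
  maximal run of ≥ 5 consecutive 1-minute bins with zero counts. From the
  bouts the package derives total sleep, episode count, mean/max episode
  duration, latency from each lights transition, mean wake-run length and
  the activity index (counts per waking minute), per fly × day × period
  (24 h / light period / dark period), then averages days within flies
  before summarising across flies (mean ± SEM).
* **Locomotor and spatial analytics** — binned distance (mm) and speed
  (mm/s), percent of the population active, capture-rate decimation
  (`subsample_distance`), and place preference: dwell seconds per tube
  section (10 equal sections, section 10 abutting the food) per time bin,
  optionally conditioned on sleep/wake state.
* **Synthetic ground truth** — a seeded two-state (rest/active) circadian
  trajectory simulator and frame renderer, so the whole pipeline is testable
  end-to-end without recorded video.

File formats: a versioned tab-delimited 1 Hz coordinate dialect, the
32-channel Trikinetics-style DAM monitor text layout (read and write), PNG
frame sequences, YAML configs.

## Worked example

Simulate two days of a wild-type-like fly, score movement at the 50% FBL
threshold, and compute the sleep panel:

```r
library(flytrackr)
library(dplyr)

sim     <- simulate_trajectory(sim_params(seed = 7, days = 2))
act     <- classify_movement(sim$trajectory,
                             min_px = fbl_threshold(10, 0.5),   # 5 px
                             max_px = fbl_threshold(10, 1.5))   # 15 px
counts  <- bin_counts(act, sim$schedule)
metrics <- sleep_metrics(counts, sim$schedule)
print(metrics, n = 6)
#> # A tibble: 6 × 11
#>   fly_id   day period total_sleep_min episode_count mean_episode_min
#>   <chr>  <int> <chr>            <int>         <int>            <dbl>
#> 1 sim1       0 FULL24             848            47             18.0
#> 2 sim1       0 LP                 291            23             12.7
#> 3 sim1       0 DP                 557            24             23.2
#> 4 sim1       1 FULL24             796            39             20.4
#> 5 sim1       1 LP                 257            20             13.2
#> 6 sim1       1 DP                 539            19             27.9
```

The fly sleeps ~820 min/day, two-thirds of it at night in longer episodes
(DP mean ~25 min vs LP ~13 min) — the light/dark architecture the simulator
is parameterised to produce. Distance and place preference from the same
trajectory:

```r
dist <- distance_series(sim$trajectory, sim$cal, sim$schedule, max_px = 15)
sum(dist$distance_mm[dist$day == 0])
#> [1] 63417      # ~63 m travelled on day 0

pr <- occupancy_proportions(occupancy(sim$trajectory, sim$cal, sim$schedule))
pr$fraction[10]
#> [1] 0.523      # half its time in the food-adjacent section
```

`average_across_days()` then gives per-fly means and group mean ± SEM
(`tidy()`/`glance()`/`autoplot()` methods included), and
`plot_sleep_timecourse()`, `plot_occupancy()`, `plot_distance()` and
`plot_percent_active()` render the standard figures.

A command-line wrapper covering the same pipeline
(`simulate | track | analyze | report`) is installed at
`system.file("cli", "flytrackr", package = "flytrackr")`; see
`?flytrackr_cli` and the example config in `inst/extdata/`.

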