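---
title: "Methods: tracking, movement thresholds, and sleep scoring in flytrackr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, movement thresholds, and sleep scoring in flytrackr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrackr)
```

`flytrackr` scores fly sleep and locomotion from 1 Hz video-derived
coordinates and compares them with infrared-beam (DAM) counts. This
vignette documents the models and procedures, the parameters that matter,
the numerical conventions, and the choices made where the design was
genuinely open — in enough detail that a user can judge what a result does
and does not mean.

## 1. The tracking model

Tracking assumes a *static* scene: a dark fly on a light background, one
fly per rectangular ROI, camera and illumination fixed for the whole
recording.

1. **Reference image.** `build_reference()` takes the pixel-wise *median*
   of one or more fly-free frames. The median (rather than a mean or a
   single snapshot) makes the reference robust when a fly transiently
   occupies a tube in some of the calibration frames. The reference is
   never updated afterwards; slow illumination drift is therefore a known
   failure mode (see §7).
2. **Foreground.** A pixel is foreground when
   `|frame − reference| > contrast_threshold`. The default threshold of 60
   (8-bit units) sits far below the rendered fixture contrast (180) and
   far above typical sensor noise, but it is rig-dependent and deliberately
   config-exposed: it has not been validated against any particular camera.
3. **Detection.** Foreground pixels inside the job's ROI are grouped into
   **8-connected** components; components with area outside
   `[min_area, max_area]` (defaults 5–400 px) are discarded as noise or
   smears. The largest survivor is the fly. Ties on area are broken by the
   smaller top-left bounding-box corner (row, then column) so output is
   deterministic. The centroid is the arithmetic mean of member pixel
   coordinates and is kept *fractional*: quantising to whole pixels would
   alias displacements near the movement threshold.
4. **Failure policy.** When no component survives, the record carries the
   last known position with `valid = FALSE`. Downstream stages never score
   displacement across an invalid record, so a dropout can only remove
   movement, not invent it. Runs of more than 60 s of invalid data flag
   their minute bins for QC.
5. **Body length.** `estimate_fbl()` is the median over detections of the
   component's largest pairwise pixel-centre distance plus one pixel (the
   pixel *extent*: an ellipse spanning 10 columns measures 10). The median
   resists frames where the fly is foreshortened on the tube wall.

Coordinates are 0-based pixels, origin top-left, y downward. The tube axis
is the longer ROI dimension; all 1-D analyses (beam, sections, the mm
calibration) project onto it.

## 2. Movement thresholds in FBL units

Per-second displacement is the full 2-D Euclidean distance between
consecutive centroids (the tube is only 5 mm wide, so the transverse
component is small but it is real movement; projecting it away would bias
distance low). A second scores movement when

```
min_px <= d_t <= max_px
```

with both cutoffs expressed as fractions of the fly body length and
converted by *round-half-up, floored at 1 px*: for a 10 px fly, 20%, 50%
and 100% give 2, 5, 10 px, and the 150% artifact cutoff gives 15 px. The
minimum is inclusive — the fly must move *at least* the threshold distance.
Displacements above `max_px` are physically unattainable within one second
and are scored as non-movement with an `artifact` flag; they are logged,
not clamped, because they indicate tracking error, not behaviour.

The threshold trade-off is the central measurement question: 1-px
sensitivity scores camera noise and postural twitches as activity, while
beam-equivalent resolution misses most real locomotion. The package treats
the fraction as the user's sensitivity dial (50% is the config default) and
makes the monotonicity explicit: raising `min_px` can only turn 1s into 0s,
so total sleep is non-decreasing in the threshold — a property the test
suite checks per fly and per period.

## 3. Virtual beam

`virtual_beam()` places a software beam at the physical beam's tube-axis
coordinate (default: the ROI axis midpoint, where DAM monitors bisect the
tube). A second emits one event when consecutive axis positions lie
*strictly* on opposite sides, or when the fly lands exactly on the beam
coming from off-beam. Consecutive on-beam samples count once: a fly resting
on the beam is not a train of crossings. The exact-landing convention is a
choice — with sub-pixel centroids the event has measure zero, so the
convention is documented rather than consequential. On simulator output the
virtual beam must reproduce the ground-truth crossing log exactly, and its
binned counts survive a DAM-file round-trip unchanged; both are asserted in
the tests.

## 4. Sleep scoring

Activity counts are summed into bins aligned to **ZT 0 (lights-on)**;
light intervals are half-open (`[on, off)`: ZT 0 is light, the lights-off
minute is dark), and only complete bins are analysed. Sleep uses the
field-standard rule: a bout is a maximal run of ≥ 5 consecutive zero-count
minutes. Anchoring analysis days at ZT 0 (rather than recording start) is
our convention; recordings must begin at or after the first lights-on, and
any earlier prefix is rejected as unentrained.

Per fly × complete day × period (FULL24, LP, DP) the package reports total
sleep, episode count, mean and max episode duration, latency, mean wake-run
length, and the activity index. Two period-attribution conventions keep the
table internally consistent:

* **Totals split at the boundary.** Minutes of a bout spanning lights-off
  are attributed to the period they fall in, so LP + DP totals always add
  to the 24 h total.
* **Episodes belong to their onset.** Counts, mean/max duration and latency
  use bouts whose *onset* lies in the period, so a boundary-spanning bout
  is one episode, not two.

Latency is measured from the period's lights transition to the first bout
onset in that period and is *capped at the period length* when no such bout
exists (flagged via `latency_capped`), so sleepless periods do not become
missing values that silently shrink group means. Latency for FULL24 is
undefined (no anchoring transition) and reported as `NA`. The activity
index is `NA` for a period with no waking minutes.

`average_across_days()` averages days *within* flies first and only then
summarises across flies; flies, not fly-days, are the unit of replication.
Dispersion is reported as SEM. Inferential statistics are deliberately out
of scope — the tidy per-fly table is the interface to whatever model the
user prefers.

## 5. Spatial analytics

Distances convert pixels to mm through the linear map of the ROI axis
extent onto the physical tube length (65 mm default). Artifact-flagged
steps contribute zero distance rather than being interpolated.
`subsample_distance()` decimates the 1 Hz trajectory to every *k*-th sample
and sums the resulting polyline; by the triangle inequality this never
exceeds the 1 Hz total and is strictly smaller whenever the fly reverses
within a stride — which is why low capture rates under-report distance.

Place preference divides the tube axis into 10 equal half-open sections
numbered toward the food (section 10 abuts the food plug; the food-end
boundary point belongs to section 10). Occupancy is dwell seconds per
section per time bin over valid tracked seconds, optionally conditioned on
sleep/wake state at minute resolution. All three matrices (unconditioned,
asleep, awake) share one grid, so the state-conditioned pair partitions the
total cell-wise — an invariant the tests assert. Because it is unstated
whether published dwell heatmaps pool or average across flies, the plotting
function offers both (`pooled = TRUE/FALSE`).

## 6. The synthetic generator: what it emulates and what it does not

`simulate_trajectory()` draws alternating rest/active bouts with
exponential durations whose means follow a 24 h square wave — the minimal
memoryless model that still produces circadian structure and makes the
expected rest fraction analytic
(`rest_mean / (rest_mean + active_mean)` per phase). Defaults, fixed once
as plausible wild-type-like conditions:

| parameter | default | rationale |
|---|---|---|
| rest/active mean bout, light | 10 / 10 min | 50% daytime rest: an active day with a siesta-scale rest load |
| rest/active mean bout, dark | 25 / 5 min | ~83% nighttime rest in consolidated episodes |
| tube axis | 260 px (65 mm, 4 px/mm) | consistent with a 10 px body on a ~2.5 mm fly |
| active step | \|N(8, 2)\| px/s | ~2 mm/s walking; ~60 m/day — realistic totals |
| food-direction probability | 0.6 | reproduces the sleep-near-food place preference |
| rest jitter SD | 0.3 px | centroid wobble far below the 2 px (20% FBL) threshold |
| rendering | fly 40 on background 220 | arbitrary fixture contrast, far above threshold 60 |

The expected ~66% daily rest fraction and the resulting ~820 scored sleep
minutes per simulated day sit in the wild-type range, and realized rest
fractions across seeds are checked against the analytic expectation in the
tests. Ground truth for validation is derived from the state labels: a
minute is truly immobile when all 60 of its seconds are rest, and runs of
≥ 5 such minutes are ground-truth sleep; with the default jitter the scored
pipeline recovers those minutes to well within 2%.

What the generator does **not** emulate: grooming and postural
micro-movements (the main real-world cause of threshold sensitivity),
feeding, tube-wall climbing and the foreshortening it causes, illumination
drift, occlusions, and multi-fly interference. Passing the recovery tests
therefore validates the *pipeline arithmetic* — tracking, thresholding,
binning, bout logic — not the behavioural realism of any particular
threshold choice on real video.

## 7. Numerical conventions and degenerate inputs

* Round-half-up for FBL thresholds (`floor(x + 0.5)`), floored at 1 px; the
  mapping of 20% of a 10 px fly to 2 px is exact under this rule.
* Half-open light intervals; half-open sections with the single food-end
  boundary point closed into section 10.
* Strict sign change for beam crossings; exact landing counts once.
* Incomplete bins and incomplete days are dropped, never padded.
* Empty inputs error early (`empty trajectory`, `no frames`, zero dwell);
  absence of a detection is a valid outcome, not an error.
* Determinism: one seeded RNG stream per simulation; tracking identical
  frames yields byte-identical records; coordinate files round-trip at 17
  significant digits.

## 8. Problem sizes

The validation suite simulates 1-day trajectories (86 400 records) for the
beam-fidelity (10 seeds) and threshold-monotonicity (20 seeds) checks, a
3-day trajectory for sleep recovery, 500 rendered frames (clean and at
noise SD 5) for tracking recovery, and 100 sixty-second random walks for
the decimation inequality — sizes chosen so the full suite exercises every
pipeline stage end-to-end in well under a minute per property on a laptop
core.

## 9. Known limitations

* Static reference: slow lighting drift degrades detection; re-run the
  reference capture rather than expecting background adaptation.
* One fly per ROI by design; identity maintenance across flies is out of
  scope.
* The coordinate-file dialect is this package's own (versioned, documented
  in `?write_coordinates`); the DAM writer targets the common 42-column
  Trikinetics text layout but is not a byte-level emulation of DAMFileScan
  output beyond it.
* Sleep scoring inherits every caveat of the 5-minute immobility proxy;
  the package measures immobility, not brain state.
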