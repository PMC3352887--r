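#' Read an experiment configuration
#'
#' The YAML config carries the light schedule, the movement-threshold
#' settings (as FBL fractions, never raw pixels, so they transfer across
#' rigs) and one block per tube: ROI, FBL, food end, optional beam position
#' and detection parameters. Overlapping ROIs are rejected up front — each
#' track job must be a discrete area containing a single fly.
#'
#' @param path Path to a YAML file (see
#'   `system.file("extdata", "example-config.yaml", package = "flytrackr")`).
#' @return A list with `schedule` ([light_schedule()]), `thresholds`
#'   (`min_fraction`, `max_fraction`), `jobs` (named list of [track_job()])
#'   and `calibrations` (named list of [calibration()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  s <- cfg$schedule %||% list()
  schedule <- light_schedule(
    lights_on_s = s$lights_on_s %||% 0,
    photoperiod_min = s$photoperiod_min %||% 720,
    cycle_min = s$cycle_min %||% 1440
  )
  th <- cfg$thresholds %||% list()
  thresholds <- list(min_fraction = th$min_fraction %||% 0.5,
                     max_fraction = th$max_fraction %||% 1.5)
  if (thresholds$min_fraction <= 0 ||
      thresholds$min_fraction > thresholds$max_fraction) {
    stop("invalid FBL fractions: need 0 < min_fraction <= max_fraction",
         call. = FALSE)
  }
  if (is.null(cfg$jobs) || length(cfg$jobs) == 0) {
    stop("config declares no track jobs", call. = FALSE)
  }
  tube_mm <- cfg$tube_length_mm %||% 65
  jobs <- list(); cals <- list()
  for (j in cfg$jobs) {
    if (is.null(j$fly_id) || is.null(j$roi) || is.null(j$fbl_px)) {
      stop("each job needs fly_id, roi and fbl_px", call. = FALSE)
    }
    roi <- unlist(j$roi)[c("xmin", "xmax", "ymin", "ymax")]
    jobs[[j$fly_id]] <- track_job(
      fly_id = j$fly_id, roi = roi,
      contrast_threshold = j$contrast_threshold %||% 60,
      min_area = j$min_area %||% 5, max_area = j$max_area %||% 400
    )
    cals[[j$fly_id]] <- calibration(
      roi = roi, fbl_px = j$fbl_px, food_end = j$food_end %||% "high",
      beam_x = j$beam_x, tube_length_mm = tube_mm
    )
  }
  check_disjoint_jobs(jobs)
  list(schedule = schedule, thresholds = thresholds, jobs = jobs,
       calibrations = cals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
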