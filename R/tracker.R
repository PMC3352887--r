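#' Define a track job
#'
#' One track job is one ROI containing exactly one fly, processed
#' independently. ROIs of distinct jobs must not overlap; [track_stream()]
#' and the config reader enforce this.
#'
#' @param fly_id Identifier for the fly.
#' @param roi ROI rectangle as for [calibration()] (`xmin`, `xmax`, `ymin`,
#'   `ymax`, 0-based pixels, half-open).
#' @param contrast_threshold Minimum absolute intensity difference from the
#'   reference image for a pixel to count as foreground. Default 60 (8-bit
#'   units); not validated against any particular rig — tune to your
#'   contrast.
#' @param min_area,max_area Accepted connected-component area range in
#'   pixels; components outside it are ignored as noise or artifacts.
#' @return An object of class `track_job`.
#' @export
track_job <- function(fly_id, roi, contrast_threshold = 60,
                      min_area = 5, max_area = 400) {
  stopifnot(contrast_threshold > 0, min_area >= 1, max_area >= min_area)
  roi <- as.list(roi)
  roi <- lapply(roi[c("xmin", "xmax", "ymin", "ymax")], as.numeric)
  stopifnot(roi$xmin < roi$xmax, roi$ymin < roi$ymax)
  structure(list(fly_id = as.character(fly_id), roi = roi,
                 contrast_threshold = contrast_threshold,
                 min_area = min_area, max_area = max_area),
            class = "track_job")
}

rois_overlap <- function(a, b) {
  a$xmin < b$xmax && b$xmin < a$xmax && a$ymin < b$ymax && b$ymin < a$ymax
}

check_disjoint_jobs <- function(jobs) {
  if (length(jobs) < 2) return(invisible(TRUE))
  for (i in seq_along(jobs)[-1]) {
    for (j in seq_len(i - 1)) {
      if (rois_overlap(jobs[[i]]$roi, jobs[[j]]$roi)) {
        stop("track jobs '", jobs[[j]]$fly_id, "' and '", jobs[[i]]$fly_id,
             "' have overlapping ROIs; each job must be a discrete, ",
             "non-overlapping area containing a single fly", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Build a reference image from fly-free frames
#'
#' The reference is the pixel-wise median of the supplied frames, which is
#' robust to a fly transiently occupying a tube in some of them.
#'
#' @param frames A list of numeric matrices (grayscale intensity grids) of
#'   identical dimensions, or a single matrix.
#' @return A matrix of the same dimensions.
#' @export
build_reference <- function(frames) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("no frames supplied", call. = FALSE)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("frames differ in shape", call. = FALSE)
  }
  if (length(frames) == 1) return(frames[[1]])
  arr <- array(unlist(frames), dim = c(d, length(frames)))
  apply(arr, c(1, 2), median)
}

#' Threshold the difference between a frame and the reference
#'
#' @param frame,reference Numeric matrices of identical dimensions.
#' @param contrast_threshold Positive intensity difference threshold.
#' @return A logical matrix, `TRUE` where
#'   `|frame - reference| > contrast_threshold`.
#' @export
difference_mask <- function(frame, reference, contrast_threshold) {
  if (!identical(dim(frame), dim(reference))) {
    stop("frame and reference differ in shape", call. = FALSE)
  }
  stopifnot(contrast_threshold > 0)
  abs(frame - reference) > contrast_threshold
}

# Label 8-connected components among sparse pixel coordinates.
# px, py are 0-based column/row coordinates; returns an integer label per
# pixel. Union-find over the (few) foreground pixels keeps this fast even
# though it runs once per frame.
label_components8 <- function(px, py) {
  n <- length(px)
  if (n == 0) return(integer(0))
  width <- max(px) - min(px) + 3
  key <- (py - min(py) + 1) * width + (px - min(px) + 1)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- c(-width - 1, -width, -width + 1, -1, 1,
               width - 1, width, width + 1)
  for (off in offsets) {
    j <- match(key + off, key)
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Detect the fly in a difference mask
#'
#' Foreground pixels inside the job's ROI are grouped into 8-connected
#' components; components with area in `[min_area, max_area]` survive and the
#' largest (area ties broken by the smaller top-left bounding-box corner,
#' row then column) is returned. The centroid is the arithmetic mean of the
#' member pixel coordinates (sub-pixel, 0-based); `major_axis_px` is the
#' component's largest pairwise pixel-centre distance plus one pixel, i.e.
#' its longest extent.
#'
#' @param mask Logical matrix over the full frame (as from
#'   [difference_mask()]).
#' @param job A [track_job()].
#' @return A one-row tibble with `x`, `y`, `area`, `bbox_xmin`, `bbox_xmax`,
#'   `bbox_ymin`, `bbox_ymax`, `major_axis_px`, or `NULL` when no component
#'   survives the size filter (a valid outcome, not an error).
#' @export
detect_fly <- function(mask, job) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  px <- idx[, 2] - 1  # 0-based x (column)
  py <- idx[, 1] - 1  # 0-based y (row)
  roi <- job$roi
  keep <- px >= roi$xmin & px < roi$xmax & py >= roi$ymin & py < roi$ymax
  px <- px[keep]; py <- py[keep]
  if (length(px) == 0) return(NULL)
  lab <- label_components8(px, py)
  areas <- tabulate(lab)
  ok <- which(areas >= job$min_area & areas <= job$max_area)
  if (length(ok) == 0) return(NULL)
  if (length(ok) > 1) {
    bx <- vapply(ok, function(l) min(px[lab == l]), numeric(1))
    by <- vapply(ok, function(l) min(py[lab == l]), numeric(1))
    ord <- order(-areas[ok], by, bx)
    ok <- ok[ord]
  }
  l <- ok[1]
  mx <- px[lab == l]; my <- py[lab == l]
  major <- if (length(mx) == 1) 1 else max(dist(cbind(mx, my))) + 1
  tibble::tibble(
    x = mean(mx), y = mean(my), area = length(mx),
    bbox_xmin = min(mx), bbox_xmax = max(mx),
    bbox_ymin = min(my), bbox_ymax = max(my),
    major_axis_px = major
  )
}

#' Track flies through a frame stream
#'
#' Each frame is compared against the static reference image; for every job
#' the fly is detected in its ROI and one record is emitted per tick. When
#' detection fails, the last known position is carried forward and the record
#' is flagged `valid = FALSE`; downstream movement scoring skips
#' displacement across invalid ticks, so carried-forward positions are never
#' scored as movement.
#'
#' @param frames A list of grayscale matrices, or a function that returns the
#'   next frame (or `NULL` at end of stream) on each call.
#' @param jobs A list of [track_job()]s with pairwise disjoint ROIs.
#' @param reference Reference image matrix (see [build_reference()]).
#' @param interval_s Capture interval in seconds between frames (default 1).
#' @param t0 Experiment time of the first frame, seconds.
#' @return A tibble of track records: `fly_id`, `t`, `x`, `y`, `valid`.
#'   Positions are `NA` until a fly's first successful detection.
#' @export
track_stream <- function(frames, jobs, reference, interval_s = 1, t0 = 0) {
  if (inherits(jobs, "track_job")) jobs <- list(jobs)
  check_disjoint_jobs(jobs)
  next_frame <- if (is.function(frames)) {
    frames
  } else {
    i <- 0
    function() {
      i <<- i + 1
      if (i > length(frames)) NULL else frames[[i]]
    }
  }
  last <- lapply(jobs, function(j) c(NA_real_, NA_real_))
  out <- vector("list", 256)
  n <- 0
  t <- t0
  repeat {
    fr <- next_frame()
    if (is.null(fr)) break
    recs <- purrr::map2_dfr(jobs, seq_along(jobs), function(job, k) {
      mask <- difference_mask(fr, reference, job$contrast_threshold)
      det <- detect_fly(mask, job)
      if (is.null(det)) {
        tibble::tibble(fly_id = job$fly_id, t = t,
                       x = last[[k]][1], y = last[[k]][2], valid = FALSE)
      } else {
        last[[k]] <<- c(det$x, det$y)
        tibble::tibble(fly_id = job$fly_id, t = t,
                       x = det$x, y = det$y, valid = TRUE)
      }
    })
    n <- n + 1
    if (n > length(out)) out <- c(out, vector("list", length(out)))
    out[[n]] <- recs
    t <- t + interval_s
  }
  dplyr::bind_rows(out[seq_len(n)])
}

#' Estimate fly body length from detections
#'
#' The FBL is the median `major_axis_px` over a sequence of detections; using
#' the median makes the estimate robust to frames where the fly is
#' foreshortened (climbing the tube wall) or partially occluded.
#'
#' @param detections A tibble of detections with a `major_axis_px` column
#'   (rows as returned by [detect_fly()]).
#' @return FBL in pixels.
#' @export
estimate_fbl <- function(detections) {
  if (is.null(detections) || nrow(detections) == 0) {
    stop("no detections to estimate FBL from", call. = FALSE)
  }
  median(detections$major_axis_px)
}
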