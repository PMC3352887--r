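#' Tube calibration: ROI, fly body length, beam and food positions
#'
#' A calibration ties one tube's region of interest (ROI) to physical units.
#' Coordinates are 0-based pixels with the origin at the frame's top-left
#' corner and y increasing downward; a pixel in column c, row r has centre
#' coordinate (c, r). The ROI is the half-open rectangle
#' `[xmin, xmax) x [ymin, ymax)` in those units. The tube axis is the longer
#' ROI dimension; all one-dimensional analyses (virtual beam, tube sections,
#' the px-to-mm map) project positions onto it.
#'
#' @param roi Named numeric vector or list with `xmin`, `xmax`, `ymin`,
#'   `ymax` (pixels, `xmin < xmax`, `ymin < ymax`).
#' @param fbl_px Fly body length in pixels (> 0). Movement thresholds are
#'   expressed as fractions of this length so settings transfer between
#'   camera setups.
#' @param food_end Which end of the tube axis holds the food plug: `"high"`
#'   (larger axis coordinate) or `"low"`.
#' @param beam_x Position of the (virtual) infrared beam on the tube axis,
#'   pixels. Defaults to the axis midpoint, where DAM monitors bisect the
#'   tube.
#' @param tube_length_mm Physical tube length in mm (default 65).
#' @return An object of class `calibration`.
#' @examples
#' cal <- calibration(roi = c(xmin = 0, xmax = 650, ymin = 0, ymax = 50),
#'                    fbl_px = 10)
#' px_to_mm(10, cal)
#' @export
calibration <- function(roi, fbl_px, food_end = c("high", "low"),
                        beam_x = NULL, tube_length_mm = 65) {
  food_end <- match.arg(food_end)
  roi <- as.list(roi)
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(roi)))
  roi <- lapply(roi[c("xmin", "xmax", "ymin", "ymax")], as.numeric)
  stopifnot(roi$xmin < roi$xmax, roi$ymin < roi$ymax,
            fbl_px > 0, tube_length_mm > 0)
  axis <- if ((roi$xmax - roi$xmin) >= (roi$ymax - roi$ymin)) "x" else "y"
  lo <- if (axis == "x") roi$xmin else roi$ymin
  hi <- if (axis == "x") roi$xmax else roi$ymax
  if (is.null(beam_x)) beam_x <- (lo + hi) / 2
  if (beam_x < lo || beam_x > hi) {
    stop("beam_x must lie on the tube axis inside the ROI", call. = FALSE)
  }
  structure(
    list(roi = roi, fbl_px = as.numeric(fbl_px), food_end = food_end,
         beam_x = as.numeric(beam_x), tube_length_mm = as.numeric(tube_length_mm),
         axis = axis, axis_min = lo, axis_max = hi),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> ROI [%g,%g)x[%g,%g) px, axis %s, FBL %g px, beam at %g, food %s end, tube %g mm\n",
    x$roi$xmin, x$roi$xmax, x$roi$ymin, x$roi$ymax, x$axis, x$fbl_px,
    x$beam_x, x$food_end, x$tube_length_mm))
  invisible(x)
}

# Project (x, y) onto the tube axis.
axis_position <- function(x, y, cal) {
  if (cal$axis == "x") x else y
}

#' Convert a tube-axis length from pixels to millimetres
#'
#' The ROI's axis extent is mapped linearly onto the physical tube length.
#'
#' @param axis_px Length(s) along the tube axis, pixels.
#' @param cal A [calibration()].
#' @return Length(s) in mm.
#' @export
px_to_mm <- function(axis_px, cal) {
  span <- cal$axis_max - cal$axis_min
  if (span <= 0) stop("degenerate ROI: zero axis extent", call. = FALSE)
  axis_px * cal$tube_length_mm / span
}

#' Tube section of an axis position
#'
#' The tube axis is divided into `n_sections` equal half-open sections.
#' Section indices increase toward the food: section `n_sections` abuts the
#' food plug and section 1 is the far end. The food-end boundary point
#' belongs to section `n_sections`.
#'
#' @param axis_px Axis position(s), pixels, within the ROI axis extent.
#' @param cal A [calibration()].
#' @param n_sections Number of equal sections (default 10).
#' @return Integer section index/indices in `1:n_sections`.
#' @export
section_of <- function(axis_px, cal, n_sections = 10) {
  if (any(axis_px < cal$axis_min | axis_px > cal$axis_max)) {
    stop("axis position outside the ROI", call. = FALSE)
  }
  span <- cal$axis_max - cal$axis_min
  frac_to_food <- if (cal$food_end == "high") {
    (axis_px - cal$axis_min) / span
  } else {
    (cal$axis_max - axis_px) / span
  }
  pmin(n_sections, as.integer(floor(frac_to_food * n_sections)) + 1L)
}
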