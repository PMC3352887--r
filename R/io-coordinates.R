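#' Write a 1 Hz coordinate file
#'
#' The coordinate file is a versioned, self-describing tab-delimited dialect:
#' comment headers carry the schema version, the job (fly) identifiers, the
#' experiment start second and the capture interval; each data row is one
#' tick with an `x`, `y`, `valid` triple per fly. Coordinates are written
#' with 17 significant digits so sub-pixel centroids round-trip exactly.
#'
#' @param traj Track-record tibble (`fly_id`, `t`, `x`, `y`, `valid`); all
#'   flies must share the same tick grid.
#' @param path Output file path.
#' @param interval_s Capture interval, seconds.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(traj, path, interval_s = 1) {
  if (nrow(traj) == 0) {
    writeLines(c("# flytrackr-coordinates v1", "# start_s: 0",
                 paste0("# interval_s: ", interval_s), "# jobs: ", "t"),
               path)
    return(invisible(path))
  }
  ids <- unique(traj$fly_id)
  ts <- sort(unique(traj$t))
  wide <- traj |>
    dplyr::mutate(valid = as.integer(.data$valid)) |>
    tidyr::pivot_wider(id_cols = "t", names_from = "fly_id",
                       values_from = c("x", "y", "valid"),
                       names_glue = "{fly_id}_{.value}") |>
    dplyr::arrange(.data$t)
  cols <- as.vector(t(outer(ids, c("x", "y", "valid"), paste, sep = "_")))
  wide <- wide[, c("t", cols)]
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(
    "# flytrackr-coordinates v1",
    paste0("# start_s: ", if (length(ts)) ts[1] else 0),
    paste0("# interval_s: ", interval_s),
    paste0("# jobs: ", paste(ids, collapse = "\t")),
    paste(c("t", cols), collapse = "\t")
  )
  if (nrow(wide) > 0) {
    body <- do.call(paste, c(lapply(names(wide), function(nm) {
      v <- wide[[nm]]
      if (nm == "t" || grepl("_valid$", nm)) {
        ifelse(is.na(v), "NA", format(v, scientific = FALSE, trim = TRUE))
      } else num(v)
    }), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a 1 Hz coordinate file
#'
#' @param path Path written by [write_coordinates()].
#' @return Track-record tibble `fly_id`, `t`, `x`, `y`, `valid`.
#' @export
read_coordinates <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# flytrackr-coordinates v1", lines[1])) {
    stop("not a flytrackr coordinate file (version header missing): ", path,
         call. = FALSE)
  }
  hdr <- grep("^#", lines)
  jobs_line <- lines[grep("^# jobs:", lines)[1]]
  ids <- strsplit(sub("^# jobs: ?", "", jobs_line), "\t")[[1]]
  col_line <- max(hdr) + 1
  if (col_line > length(lines)) {
    return(tibble::tibble(fly_id = character(0), t = numeric(0),
                          x = numeric(0), y = numeric(0), valid = logical(0)))
  }
  cols <- strsplit(lines[col_line], "\t")[[1]]
  body <- lines[-seq_len(col_line)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble::tibble(fly_id = character(0), t = numeric(0),
                          x = numeric(0), y = numeric(0), valid = logical(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad) > 0) {
    stop("malformed coordinate row at line ", col_line + bad[1], " of ",
         path, " (expected ", length(cols), " fields)", call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols
  purrr::map_dfr(ids, function(id) {
    tibble::tibble(
      fly_id = id,
      t = m[, "t"],
      x = m[, paste0(id, "_x")],
      y = m[, paste0(id, "_y")],
      valid = m[, paste0(id, "_valid")] == 1
    )
  })
}

#' Read or write grayscale frames as PNG files
#'
#' Frames are stored as 8-bit grayscale PNG files named
#' `frame_000001.png, ...` in a directory; intensities map 0–255 to 0–1.
#'
#' @param frames List of matrices (0–255).
#' @param dir Directory to write into (created if needed).
#' @return `write_frames()`: the directory, invisibly. `read_frames()`: a
#'   list of matrices.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' @param pattern Filename glob for frame files.
#' @rdname write_frames
#' @export
read_frames <- function(dir, pattern = "frame_*.png") {
  files <- sort(Sys.glob(file.path(dir, pattern)))
  if (length(files) == 0) stop("no frames matching ", pattern, " in ", dir,
                               call. = FALSE)
  purrr::map(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) {
      # ITU-R 601 luma conversion for color input
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    round(img * 255)
  })
}
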