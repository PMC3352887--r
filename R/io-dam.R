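DAM_N_CHANNELS <- 32L
DAM_N_META <- 10L  # reading index, date, time, status, six spare fields

dam_date <- function(dt) {
  lt <- as.POSIXlt(dt, tz = "UTC")
  sprintf("%d %s %02d", lt$mday, month.abb[lt$mon + 1], lt$year %% 100)
}

parse_dam_datetime <- function(date_s, time_s) {
  parts <- strsplit(date_s, " ", fixed = TRUE)
  day <- as.integer(vapply(parts, `[`, "", 1))
  mon <- match(vapply(parts, `[`, "", 2), month.abb)
  yr <- 2000L + as.integer(vapply(parts, `[`, "", 3))
  as.POSIXct(sprintf("%04d-%02d-%02d %s", yr, mon, day, time_s), tz = "UTC")
}

#' Write counts as a Trikinetics-style DAM monitor file
#'
#' Emits the 32-channel tab-delimited monitor dialect: each row is one
#' reading (one bin) with a reading index, date (`D Mon YY`), time
#' (`HH:MM:SS`), a status field, six spare zero fields, then 32 integer
#' channel counts. Flies are assigned to channels in order of appearance;
#' unused channels are zero-filled. More than 32 flies are split across
#' files with numeric suffixes (`monitor_1.txt`, `monitor_2.txt`, ...).
#'
#' @param counts Binned counts from [bin_counts()] (columns `fly_id`,
#'   `bin_start_min`, `count`); all flies must share a common bin grid.
#' @param path Output path (used as a stem when splitting).
#' @param anchor POSIXct mapping `bin_start_min = 0`; rows are timestamped
#'   `anchor + bin_start_min` minutes.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_dam <- function(counts, path,
                      anchor = as.POSIXct("2026-01-01 08:00:00",
                                          tz = "UTC")) {
  if (any(counts$count < 0)) stop("negative counts", call. = FALSE)
  ids <- unique(counts$fly_id)
  wide <- counts |>
    tidyr::pivot_wider(id_cols = "bin_start_min", names_from = "fly_id",
                       values_from = "count", values_fill = 0L) |>
    dplyr::arrange(.data$bin_start_min)
  n_files <- ceiling(length(ids) / DAM_N_CHANNELS)
  paths <- if (n_files == 1) path else {
    stem <- sub("\\.([^.]+)$", "", path)
    ext <- if (grepl("\\.", basename(path))) sub("^.*\\.", ".", path) else ""
    paste0(stem, "_", seq_len(n_files), ext)
  }
  dt <- anchor + wide$bin_start_min * 60
  for (f in seq_len(n_files)) {
    ch_ids <- ids[((f - 1) * DAM_N_CHANNELS + 1):
                    min(f * DAM_N_CHANNELS, length(ids))]
    mat <- matrix(0L, nrow = nrow(wide), ncol = DAM_N_CHANNELS)
    for (k in seq_along(ch_ids)) mat[, k] <- as.integer(wide[[ch_ids[k]]])
    rows <- paste(
      seq_len(nrow(wide)), dam_date(dt), format(dt, "%H:%M:%S", tz = "UTC"),
      1L, 0L, 0L, 0L, 0L, 0L, 0L,
      apply(mat, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(rows, paths[f])
  }
  invisible(paths)
}

#' Read a Trikinetics-style DAM monitor file
#'
#' Channels are returned as flies `ch01`..`ch32` (the monitor dialect does
#' not carry fly names). Bin starts are recovered relative to `anchor`, then
#' annotated with day and light/dark period so the result feeds the sleep
#' pipeline exactly like [bin_counts()] output.
#'
#' @param path A monitor file written by [write_dam()] (or by DAMFileScan in
#'   the same 42-column layout).
#' @param schedule A [light_schedule()] for day/period annotation.
#' @param bin_length_s Bin length the file was scanned at, seconds.
#' @param anchor POSIXct corresponding to `bin_start_min = 0` (default: the
#'   timestamp of the first reading).
#' @param drop_empty Drop all-zero channels (default `TRUE`; a real monitor
#'   reports all 32 whether or not a tube is loaded). Channels that ever
#'   report a count are always kept.
#' @return Count tibble `fly_id`, `bin_start_min`, `day`, `period`,
#'   `count`, `flagged`, with attribute `bin_length_s`.
#' @export
read_dam <- function(path, schedule = light_schedule(), bin_length_s = 60,
                     anchor = NULL, drop_empty = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- DAM_N_META + DAM_N_CHANNELS
  bad <- which(lengths(parts) != nf)
  if (length(bad) > 0) {
    stop("malformed DAM row at line ", bad[1], " of ", path,
         " (expected ", nf, " fields)", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = nf, byrow = TRUE)
  dt <- parse_dam_datetime(m[, 2], m[, 3])
  if (is.null(anchor)) anchor <- dt[1]
  bin_start_min <- as.numeric(difftime(dt, anchor, units = "mins"))
  cnt <- matrix(as.integer(m[, DAM_N_META + seq_len(DAM_N_CHANNELS)]),
                ncol = DAM_N_CHANNELS)
  keep <- if (drop_empty) which(colSums(cnt) > 0) else seq_len(DAM_N_CHANNELS)
  if (length(keep) == 0) keep <- 1L
  out <- purrr::map_dfr(keep, function(k) {
    tibble::tibble(fly_id = sprintf("ch%02d", k),
                   bin_start_min = bin_start_min,
                   count = cnt[, k])
  }) |>
    dplyr::mutate(
      day = as.integer(.data$bin_start_min %/% schedule$cycle_min),
      period = period_of_zt(.data$bin_start_min %% schedule$cycle_min,
                            schedule),
      flagged = FALSE
    ) |>
    dplyr::select("fly_id", "bin_start_min", "day", "period", "count",
                  "flagged")
  attr(out, "bin_length_s") <- bin_length_s
  out
}
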