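#' Construct an IMU trial object
#'
#' An `imu_trial` is the package's container for one walking-trial recording
#' from a single ear-worn six-axis IMU: a three-channel accelerometer and a
#' three-channel gyroscope sampled on a common, regular clock.
#'
#' Channels are stored in the analysis frame used throughout the package:
#' `si` (superior-inferior, positive superior), `ml` (mediolateral, positive
#' toward the participant's left) and `ap` (anterior-posterior, positive
#' forward). Accelerations are in m/s^2 (gravity included, so a stationary
#' upright sensor reads approximately +9.81 on `si`), angular rates in deg/s.
#'
#' Samples that were absent in the raw recording (lost packets) are carried as
#' `NA` in the channels and flagged in `missing_mask`; [fill_gaps()] repairs
#' them after [detect_gaps()] has applied the data-quality exclusion rules.
#'
#' @param accel numeric matrix, n x 3, columns `si`, `ml`, `ap` (m/s^2).
#' @param gyro numeric matrix, n x 3, columns `si`, `ml`, `ap` (deg/s).
#' @param fs sampling rate in Hz (default 100).
#' @param side which ear the sensor was worn on, `"left"` or `"right"`.
#' @param missing_mask logical vector of length n marking originally absent
#'   samples; defaults to rows containing any `NA`.
#' @return An object of class `imu_trial` with fields `accel`, `gyro`, `fs`,
#'   `side`, `missing_mask` and `n` (number of samples).
#' @seealso [read_trial()], [detect_gaps()], [fill_gaps()], [simulate_trial()]
#' @export
imu_trial <- function(accel, gyro, fs = 100, side = c("left", "right"),
                      missing_mask = NULL) {
  side <- match.arg(side)
  accel <- as_channel_matrix(accel, "accel")
  gyro <- as_channel_matrix(gyro, "gyro")
  if (nrow(accel) != nrow(gyro)) {
    stop("accel and gyro must have the same number of samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  n <- nrow(accel)
  if (is.null(missing_mask)) {
    missing_mask <- rowSums(is.na(accel)) > 0 | rowSums(is.na(gyro)) > 0
  }
  missing_mask <- as.logical(missing_mask)
  if (length(missing_mask) != n) {
    stop("missing_mask length must match the number of samples", call. = FALSE)
  }
  structure(
    list(accel = accel, gyro = gyro, fs = fs, side = side,
         missing_mask = missing_mask, n = n),
    class = "imu_trial"
  )
}

as_channel_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must have 3 columns (si, ml, ap)", call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- .AXES
  x
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %d samples @ %g Hz (%.2f s), %s ear\n",
              x$n, x$fs, x$n / x$fs, x$side))
  n_miss <- sum(x$missing_mask)
  if (n_miss > 0) cat(sprintf("  %d missing sample(s)\n", n_miss))
  invisible(x)
}

#' Duration helper
#' @param trial an [imu_trial()].
#' @return trial duration in seconds.
#' @export
trial_duration <- function(trial) trial$n / trial$fs

# --- axis mapping ------------------------------------------------------------

#' Parse a device-to-analysis axis map
#'
#' Devices report accelerometer/gyroscope channels in their own mounting frame
#' (`x`, `y`, `z`). An axis map declares, for each analysis axis, which signed
#' device axis it corresponds to, e.g. `c(si = "-z", ml = "+y", ap = "+x")`
#' for a sensor whose z axis points inferior.
#'
#' @param axis_map named character vector with entries `si`, `ml`, `ap`; each
#'   value one of `"+x" "-x" "+y" "-y" "+z" "-z"` (a bare letter means `+`).
#' @return internal representation (named list of column index and sign).
#' @export
parse_axis_map <- function(axis_map = c(si = "+x", ml = "+y", ap = "+z")) {
  if (is.list(axis_map)) axis_map <- unlist(axis_map)
  if (!all(.AXES %in% names(axis_map))) {
    stop("axis_map must name all of si, ml, ap", call. = FALSE)
  }
  parse_one <- function(s) {
    s <- trimws(s)
    sign <- 1
    if (startsWith(s, "-")) { sign <- -1; s <- substring(s, 2) }
    else if (startsWith(s, "+")) s <- substring(s, 2)
    idx <- match(tolower(s), c("x", "y", "z"))
    if (is.na(idx)) stop("axis_map entries must be one of +/-x, +/-y, +/-z",
                         call. = FALSE)
    list(col = idx, sign = sign)
  }
  out <- lapply(axis_map[.AXES], parse_one)
  cols <- vapply(out, `[[`, 1L, "col")
  if (anyDuplicated(cols)) stop("axis_map maps two analysis axes to the same device axis",
                                call. = FALSE)
  out
}

apply_axis_map <- function(xyz, map) {
  out <- matrix(NA_real_, nrow(xyz), 3L, dimnames = list(NULL, .AXES))
  for (a in .AXES) out[, a] <- map[[a]]$sign * xyz[, map[[a]]$col]
  out
}

# --- CSV I/O -----------------------------------------------------------------

#' Read one trial from a delimited text file
#'
#' Expects a header row with columns `sample, accel_x, accel_y, accel_z,
#' gyro_x, gyro_y, gyro_z` (raw device frame). The `sample` column must be
#' integer and strictly increasing; skipped indices are interpreted as dropped
#' samples and inserted as missing rows, as are rows whose channels contain
#' `NA`. Device axes are remapped to the analysis frame through `axis_map`.
#'
#' @param path path to the CSV file.
#' @param axis_map device-to-analysis mapping, see [parse_axis_map()].
#' @inheritParams imu_trial
#' @return an [imu_trial()] with `missing_mask` marking absent rows.
#' @export
read_trial <- function(path, axis_map = c(si = "+x", ml = "+y", ap = "+z"),
                       fs = 100, side = "left") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample", paste0("accel_", c("x", "y", "z")),
              paste0("gyro_", c("x", "y", "z")))
  if (!all(needed %in% names(df))) {
    stop("malformed header: need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  idx <- df$sample
  if (anyNA(idx) || any(diff(idx) <= 0)) {
    stop("sample index must be strictly increasing", call. = FALSE)
  }
  idx <- as.integer(idx) - as.integer(idx[1L])  # 0-based, relative to start
  n <- idx[length(idx)] + 1L
  raw_a <- matrix(NA_real_, n, 3L)
  raw_g <- matrix(NA_real_, n, 3L)
  raw_a[idx + 1L, ] <- as.matrix(df[, needed[2:4]])
  raw_g[idx + 1L, ] <- as.matrix(df[, needed[5:7]])
  map <- parse_axis_map(axis_map)
  imu_trial(apply_axis_map(raw_a, map), apply_axis_map(raw_g, map),
            fs = fs, side = side)
}

#' Write a trial to a delimited text file
#'
#' Writes the analysis-frame channels with an identity axis map, so
#' `read_trial(write_trial(x, f), axis_map = c(si="+x", ml="+y", ap="+z"))`
#' round-trips losslessly. Missing samples are written as empty fields.
#'
#' @param trial an [imu_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  df <- data.frame(
    sample = seq_len(trial$n) - 1L,
    accel_x = trial$accel[, "si"], accel_y = trial$accel[, "ml"],
    accel_z = trial$accel[, "ap"],
    gyro_x = trial$gyro[, "si"], gyro_y = trial$gyro[, "ml"],
    gyro_z = trial$gyro[, "ap"]
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write gait-event tables
#'
#' Event tables are CSV files with columns `sample` (0-based index into the
#' trial), `event` (`IC` or `TC`) and `side` (`L`, `R` or `U` for unknown).
#'
#' @param path path to the CSV file.
#' @param source label recorded in the returned event frame (e.g. `"truth"`).
#' @return `read_events`: a gait-event data frame (see [gait_events()]).
#' @export
read_events <- function(path, source = "truth") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "event", "side") %in% names(df))) {
    stop("event table needs columns sample, event, side", call. = FALSE)
  }
  gait_events(sample = df$sample, kind = df$event, side = df$side,
              source = source)
}

#' @rdname read_events
#' @param events a gait-event data frame.
#' @export
write_events <- function(events, path) {
  df <- data.frame(sample = events$sample, event = events$kind,
                   side = events$side)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
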