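#' Per-minute epoch series
#'
#' The central container of the package: a contiguous 1-minute grid of
#' vertical-axis intensity values for one device. Minutes with no recording
#' are coded `NA` (never dropped), so downstream wear logic can distinguish
#' "not recorded" from "zero movement".
#'
#' @param values numeric vector of per-minute intensities; `NA` marks a
#'   minute that was not recorded. Non-missing values must be >= 0.
#' @param start `POSIXct` timestamp of the first epoch, aligned to a whole
#'   minute (UTC recommended).
#' @param unit measurement unit: `"counts"` (research accelerometer
#'   counts/min) or `"g"` (phone gravity-removed g/min).
#' @param device device label.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(values, start, unit = c("g", "counts"),
                         device = "device") {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("epoch_series needs at least one epoch", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("epoch intensities must be >= 0", call. = FALSE)
  if (!inherits(start, "POSIXct")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  if (as.numeric(start) %% 60 != 0)
    stop("epoch start must fall on a whole minute", call. = FALSE)
  structure(list(values = values, start = start,
                 unit = unit, device = device),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<epoch_series> device '%s', unit %s/min\n", x$device, x$unit))
  cat(sprintf("  %d epochs from %s (%d not recorded)\n", n,
              format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

#' Epoch timestamps
#'
#' @param series an [epoch_series()].
#' @return `POSIXct` vector, one timestamp per epoch (start of the
#'   half-open minute `[t, t + 60s)`).
#' @export
epoch_times <- function(series) {
  series$start + 60 * (seq_along(series$values) - 1L)
}

#' Column dialect for raw acceleration files
#'
#' Names the timestamp and axis columns of a delimited raw-stream file and
#' declares which axis is vertical. Orientation is a deployment property of
#' the waist-worn device, so it is configured, never inferred.
#'
#' @param timestamp,x,y,z column names in the file.
#' @param vertical which axis is vertical: `"x"`, `"y"` or `"z"`.
#' @param tz timezone of textual timestamps.
#' @export
raw_dialect <- function(timestamp = "timestamp", x = "ax", y = "ay",
                        z = "az", vertical = "y", tz = "UTC") {
  vertical <- match.arg(vertical, c("x", "y", "z"))
  structure(list(timestamp = timestamp, x = x, y = y, z = z,
                 vertical = vertical, tz = tz),
            class = "raw_dialect")
}

#' Construct a raw acceleration stream
#'
#' @param time `POSIXct` (or epoch seconds) sample timestamps, strictly
#'   increasing.
#' @param ax,ay,az acceleration components in g, finite.
#' @param sample_rate nominal sampling rate in Hz (> 0).
#' @param device device label.
#' @param vertical vertical axis name.
#' @return An object of class `raw_stream`.
#' @export
raw_stream <- function(time, ax, ay, az, sample_rate,
                       device = "device", vertical = "y") {
  if (!inherits(time, "POSIXct")) time <- as.POSIXct(time, tz = "UTC",
                                                     origin = "1970-01-01")
  n <- length(time)
  if (n == 0L) stop("raw stream is empty", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("axis vectors must match timestamp length", call. = FALSE)
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stop("acceleration components must be finite", call. = FALSE)
  bad <- which(diff(as.numeric(time)) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L),
         call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  structure(list(time = time, ax = ax, ay = ay, az = az,
                 sample_rate = sample_rate, device = device,
                 vertical = match.arg(vertical, c("x", "y", "z"))),
            class = "raw_stream")
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> device '%s', %d samples @ %g Hz, vertical = %s\n",
              x$device, length(x$time), x$sample_rate, x$vertical))
  invisible(x)
}

#' Read a raw tri-axial stream from a delimited text file
#'
#' Rows whose timestamp or axis fields fail to parse are dropped, counted,
#' and reported via a warning; they never enter the stream.
#'
#' @param path CSV file path.
#' @param dialect a [raw_dialect()] mapping columns.
#' @param sample_rate nominal rate in Hz; if `NULL`, estimated as the
#'   median reciprocal inter-sample interval.
#' @param device device label.
#' @return A [raw_stream()].
#' @export
read_raw_stream <- function(path, dialect = raw_dialect(),
                            sample_rate = NULL, device = "device") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c(dialect$timestamp, dialect$x, dialect$y, dialect$z)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("dialect names columns absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ts_raw <- df[[dialect$timestamp]]
  # accept epoch seconds or ISO-8601 text
  ts_num <- suppressWarnings(as.numeric(ts_raw))
  if (all(is.na(ts_num))) {
    time <- as.POSIXct(ts_raw, tz = dialect$tz,
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS"))
  } else {
    time <- as.POSIXct(ts_num, tz = "UTC", origin = "1970-01-01")
  }
  ax <- suppressWarnings(as.numeric(df[[dialect$x]]))
  ay <- suppressWarnings(as.numeric(df[[dialect$y]]))
  az <- suppressWarnings(as.numeric(df[[dialect$z]]))
  ok <- !is.na(time) & is.finite(ax) & is.finite(ay) & is.finite(az)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(sprintf("%d unparseable row(s) dropped from %s", n_bad, path),
            call. = FALSE)
  if (!any(ok)) stop("no parseable samples in ", path, call. = FALSE)
  time <- time[ok]; ax <- ax[ok]; ay <- ay[ok]; az <- az[ok]
  bad <- which(diff(as.numeric(time)) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at row %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  if (is.null(sample_rate)) {
    dt <- stats::median(diff(as.numeric(time)))
    sample_rate <- 1 / dt
  }
  raw_stream(time, ax, ay, az, sample_rate = sample_rate, device = device,
             vertical = dialect$vertical)
}

#' Write a raw stream to CSV
#'
#' @param stream a [raw_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raw_stream <- function(stream, path) {
  df <- data.frame(
    timestamp = sprintf("%.6f", as.numeric(stream$time)),
    ax = stream$ax, ay = stream$ay, az = stream$az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

vertical_axis <- function(stream) {
  switch(stream$vertical, x = stream$ax, y = stream$ay, z = stream$az)
}

#' Summarize a raw stream to 1-minute vertical-axis epochs
#'
#' Each calendar minute touched by the stream gets one value: the mean,
#' over that minute's samples, of the absolute deviation of the vertical
#' acceleration from its per-minute median. The per-minute median stands in
#' for the gravity component, so a device lying still yields 0 g/min.
#' Minutes inside the stream's span with no samples are coded `NA`.
#'
#' @param stream a [raw_stream()].
#' @return An [epoch_series()] with unit `"g"`.
#' @export
summarize_to_epochs <- function(stream) {
  if (!inherits(stream, "raw_stream")) stop("not a raw_stream", call. = FALSE)
  v <- vertical_axis(stream)
  t_num <- as.numeric(stream$time)
  minute <- floor(t_num / 60)
  first <- minute[1]; last <- minute[length(minute)]
  grid <- first:last
  idx <- match(minute, grid)
  vals <- rep(NA_real_, length(grid))
  counts <- integer(length(grid))
  for (g in unique(idx)) {
    vg <- v[idx == g]
    vals[g] <- mean(abs(vg - stats::median(vg)))
    counts[g] <- length(vg)
  }
  out <- epoch_series(vals,
                      start = as.POSIXct(first * 60, tz = "UTC",
                                         origin = "1970-01-01"),
                      unit = "g", device = stream$device)
  attr(out, "sample_counts") <- counts
  out
}

#' Read / write per-minute epoch CSV files
#'
#' The on-disk format has columns `timestamp,vt,unit,device`; timestamps
#' are ISO-8601 UTC, missing epochs carry the sentinel `NA`. The round trip
#' write -> read is lossless.
#'
#' @param path CSV file path.
#' @param unit expected unit tag (`"g"` or `"counts"`); if `NULL`, taken
#'   from the file.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "NA")
  need <- c("timestamp", "vt")
  if (!all(need %in% names(df)))
    stop("epoch CSV must have columns timestamp and vt", call. = FALSE)
  if (nrow(df) == 0L) stop("epoch CSV is empty: ", path, call. = FALSE)
  file_unit <- if ("unit" %in% names(df)) df$unit[1] else NULL
  if (is.null(unit)) unit <- file_unit
  if (is.null(unit)) stop("unit tag missing from file and call", call. = FALSE)
  if (!is.null(file_unit) && !is.na(file_unit) && file_unit != unit)
    stop(sprintf("unit mismatch: file says '%s', caller says '%s'",
                 file_unit, unit), call. = FALSE)
  vt <- as.numeric(df$vt)
  if (any(vt < 0, na.rm = TRUE))
    stop("negative intensity value in ", path, call. = FALSE)
  time <- as.POSIXct(df$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(time)) stop("unparseable timestamp in ", path, call. = FALSE)
  step <- diff(as.numeric(time))
  if (length(step) && any(step != 60))
    stop("epochs not contiguous at 1-minute spacing in ", path,
         call. = FALSE)
  device <- if ("device" %in% names(df)) df$device[1] else "device"
  epoch_series(vt, start = time[1], unit = unit, device = device)
}

#' @rdname read_epoch_csv
#' @param series an [epoch_series()] to write.
#' @export
write_epoch_csv <- function(series, path) {
  df <- data.frame(
    timestamp = format(epoch_times(series), "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC"),
    vt = series$values,
    unit = series$unit,
    device = series$device)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
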