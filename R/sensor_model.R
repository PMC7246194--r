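# Data types and file I/O for tag logs and derived orientation series.
#
# Frame convention used throughout the package (fixed once, everywhere):
# world frame is North-East-Down; the sensor frame is surge (longitudinal,
# positive forward), sway (lateral, positive to the animal's right) and
# heave (dorso-ventral, positive dorsal, i.e. up when the head is level).
# A resting accelerometer measures the gravity reaction: +1 g on heave
# when level. Orientation is intrinsic Z-Y-X: heading (clockwise from
# magnetic North), then pitch (positive nose-up), then roll (positive
# sway-side toward gravity).

#' Construct a tri-axial IMU series
#'
#' Bundles synchronized tri-axial acceleration (in g) and magnetometer
#' channels sampled at a fixed rate, the raw material for orientation
#' estimation. Magnetometer units are arbitrary; they are normalized during
#' calibration.
#'
#' @param acc_surge,acc_heave,acc_sway acceleration in g along the
#'   longitudinal, dorso-ventral and lateral axes.
#' @param mag_x,mag_y,mag_z magnetometer channels, axis-aligned with
#'   (surge, sway, heave) respectively; arbitrary units.
#' @param fs sampling rate in Hz.
#' @param t optional time stamps in seconds since start; defaults to
#'   `(0:(n-1))/fs`. Must be uniform at 1/fs within 1e-6 s.
#' @param meta free-form provenance list (tag id, placement = "head"|"body").
#' @return an object of class `imu_series`.
#' @export
imu_series <- function(acc_surge, acc_heave, acc_sway,
                       mag_x, mag_y, mag_z,
                       fs, t = NULL, meta = list()) {
  n <- length(acc_surge)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  x <- structure(
    list(t = as.numeric(t), fs = as.numeric(fs),
         acc_surge = as.numeric(acc_surge),
         acc_heave = as.numeric(acc_heave),
         acc_sway = as.numeric(acc_sway),
         mag_x = as.numeric(mag_x),
         mag_y = as.numeric(mag_y),
         mag_z = as.numeric(mag_z),
         meta = meta),
    class = "imu_series")
  validate_imu_series(x)
}

#' Validate an IMU series against its type invariants
#'
#' @param x an `imu_series`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_imu_series <- function(x) {
  if (!inherits(x, "imu_series")) format_error("not an imu_series")
  if (!is.finite(x$fs) || x$fs <= 0) format_error("fs must be > 0")
  n <- length(x$t)
  chans <- c("acc_surge", "acc_heave", "acc_sway", "mag_x", "mag_y", "mag_z")
  for (ch in chans) {
    if (length(x[[ch]]) != n)
      format_error(sprintf("channel '%s' length %d != %d", ch, length(x[[ch]]), n))
    if (!all(is.finite(x[[ch]])))
      format_error(sprintf("channel '%s' contains non-finite values", ch))
  }
  if (n > 1) {
    dt <- diff(x$t)
    bad <- which(abs(dt - 1 / x$fs) > 1e-6)
    if (length(bad))
      format_error(sprintf(
        "non-uniform timestamps: spacing %.9g s at index %d (expected %.9g s)",
        dt[bad[1]], bad[1] + 1, 1 / x$fs))
  }
  x
}

#' @export
length.imu_series <- function(x) length(x$t)

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples at %g Hz (%.1f s)\n",
              length(x$t), x$fs, if (length(x$t)) diff(range(x$t)) else 0))
  if (length(x$meta)) utils::str(x$meta, give.attr = FALSE)
  invisible(x)
}

#' @export
as.data.frame.imu_series <- function(x, ...) {
  data.frame(t = x$t, acc_surge = x$acc_surge, acc_heave = x$acc_heave,
             acc_sway = x$acc_sway, mag_x = x$mag_x, mag_y = x$mag_y,
             mag_z = x$mag_z)
}

default_column_map <- function() {
  list(t = "t", acc_surge = "acc_surge", acc_heave = "acc_heave",
       acc_sway = "acc_sway", mag_x = "mag_x", mag_y = "mag_y",
       mag_z = "mag_z")
}

#' Read a tag log from delimited text
#'
#' Reads a CSV tag log into an [imu_series()]. The column map renames the
#' log's own headers onto the canonical channels and, through per-axis sign
#' flips and unit scales, maps any tag mounting onto the canonical
#' surge/sway/heave frame (acceleration must end up in g).
#'
#' Rows containing non-numeric sensor values are rejected with a warning
#' listing their indices, and the survivors are re-gridded at `fs` from the
#' first kept timestamp; otherwise timestamps must be uniform at 1/fs.
#'
#' @param path CSV file with a header row, '.' decimal.
#' @param fs sampling rate in Hz.
#' @param column_map named list mapping canonical names (`t`, `acc_surge`,
#'   `acc_heave`, `acc_sway`, `mag_x`, `mag_y`, `mag_z`) to file column
#'   names. The `t` entry may be `NULL` to synthesize time from `fs`.
#' @param acc_scale,mag_scale multiplicative unit conversions applied after
#'   reading (e.g. 1/9.81 for logs in m/s^2).
#' @param axis_signs named numeric vector of +-1 sign flips per channel.
#' @param meta provenance list stored on the result.
#' @return an `imu_series`.
#' @export
read_imu_csv <- function(path, fs, column_map = default_column_map(),
                         acc_scale = 1, mag_scale = 1,
                         axis_signs = NULL, meta = list()) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  cm <- utils::modifyList(default_column_map(), as.list(column_map))
  need <- c("acc_surge", "acc_heave", "acc_sway", "mag_x", "mag_y", "mag_z")
  has_t <- !is.null(cm$t) && cm$t %in% names(raw)
  for (ch in need) {
    if (is.null(cm[[ch]]) || !cm[[ch]] %in% names(raw))
      config_error(sprintf("missing column '%s' (mapped to channel %s)",
                           cm[[ch]] %||% "<unset>", ch))
  }
  cols <- need
  if (has_t) cols <- c("t", cols)
  num <- lapply(cols, function(ch) suppressWarnings(as.numeric(raw[[cm[[ch]]]])))
  names(num) <- cols
  bad <- Reduce(`|`, lapply(num, function(v) !is.finite(v)))
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with non-numeric sensor values: %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
    num <- lapply(num, function(v) v[!bad])
    # surviving rows are re-gridded at fs from the first kept timestamp;
    # dropped rows would otherwise leave gaps violating uniform sampling
    if (has_t && length(num$t))
      num$t <- num$t[1] + (seq_along(num$t) - 1) / fs
  }
  sgn <- function(ch) if (!is.null(axis_signs) && ch %in% names(axis_signs))
    axis_signs[[ch]] else 1
  imu_series(
    acc_surge = num$acc_surge * acc_scale * sgn("acc_surge"),
    acc_heave = num$acc_heave * acc_scale * sgn("acc_heave"),
    acc_sway = num$acc_sway * acc_scale * sgn("acc_sway"),
    mag_x = num$mag_x * mag_scale * sgn("mag_x"),
    mag_y = num$mag_y * mag_scale * sgn("mag_y"),
    mag_z = num$mag_z * mag_scale * sgn("mag_z"),
    fs = fs, t = if (has_t) num$t else NULL, meta = meta)
}

#' Write an IMU series to CSV
#'
#' Full-precision output: re-reading with [read_imu_csv()] reproduces the
#' series exactly.
#'
#' @param x an `imu_series`.
#' @param path output file path.
#' @export
write_imu_csv <- function(x, path) {
  validate_imu_series(x)
  df <- as.data.frame(x)
  chr <- vapply(df, num_chr, character(nrow(df)))
  if (nrow(df) == 1L) chr <- matrix(chr, nrow = 1, dimnames = list(NULL, names(df)))
  ok <- tryCatch({
    utils::write.table(chr, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = names(df))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) hods_error(sprintf("cannot write to '%s'", path), "hods_io_error")
  invisible(NULL)
}

#' Construct an orientation series
#'
#' Per-sample heading, pitch and roll in degrees with validity flags.
#' Heading is clockwise from magnetic North in [0, 360); pitch positive
#' nose-up in [-90, 90]; roll in (-180, 180]. Samples flagged invalid carry
#' NaN angles but keep their time stamps so downstream windows stay uniform.
#'
#' @param heading,pitch,roll angle channels in degrees (NaN where invalid).
#' @param fs sampling rate in Hz.
#' @param t optional time stamps (seconds); defaults to `(0:(n-1))/fs`.
#' @param valid logical validity flags; defaults to all finite samples.
#' @param meta provenance list.
#' @return an object of class `orientation_series`.
#' @export
orientation_series <- function(heading, pitch, roll = NULL, fs, t = NULL,
                               valid = NULL, meta = list()) {
  n <- length(heading)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (is.null(roll)) roll <- rep(0, n)
  if (is.null(valid)) valid <- is.finite(heading) & is.finite(pitch)
  x <- structure(
    list(t = as.numeric(t), fs = as.numeric(fs),
         heading = as.numeric(heading), pitch = as.numeric(pitch),
         roll = as.numeric(roll), valid = as.logical(valid), meta = meta),
    class = "orientation_series")
  validate_orientation_series(x)
}

#' Validate an orientation series
#'
#' @param x an `orientation_series`.
#' @return `x` if valid, else an error.
#' @export
validate_orientation_series <- function(x) {
  if (!inherits(x, "orientation_series")) format_error("not an orientation_series")
  n <- length(x$t)
  for (ch in c("heading", "pitch", "roll", "valid"))
    if (length(x[[ch]]) != n) format_error(sprintf("channel '%s' wrong length", ch))
  v <- x$valid
  if (any(v & !is.finite(x$heading))) format_error("NaN heading on valid sample")
  h <- x$heading[v]; p <- x$pitch[v]; r <- x$roll[v]
  if (length(h) && (min(h) < 0 || max(h) >= 360))
    format_error("heading outside [0, 360) on valid samples")
  if (length(p) && (min(p) < -90 - 1e-9 || max(p) > 90 + 1e-9))
    format_error("pitch outside [-90, 90] on valid samples")
  if (length(r) && (min(r) <= -180 || max(r) > 180 + 1e-9))
    format_error("roll outside (-180, 180] on valid samples")
  x
}

#' @export
length.orientation_series <- function(x) length(x$t)

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples at %g Hz, %d valid (%.1f%%)\n",
              length(x$t), x$fs, sum(x$valid),
              if (length(x$t)) 100 * mean(x$valid) else 0))
  invisible(x)
}

#' @export
as.data.frame.orientation_series <- function(x, ...) {
  data.frame(t = x$t, heading_deg = x$heading, pitch_deg = x$pitch,
             roll_deg = x$roll, valid = x$valid)
}

#' Write an orientation series to CSV
#'
#' Columns `t, heading_deg, pitch_deg, roll_deg, valid`, written at full
#' precision so a read-back reproduces the series exactly.
#'
#' @param x an `orientation_series`.
#' @param path output file path.
#' @export
write_orientation_csv <- function(x, path) {
  validate_orientation_series(x)
  df <- as.data.frame(x)
  chr <- cbind(num_chr(df$t), num_chr(df$heading_deg), num_chr(df$pitch_deg),
               num_chr(df$roll_deg), ifelse(df$valid, "TRUE", "FALSE"))
  ok <- tryCatch({
    utils::write.table(chr, path, sep = ",", quote = FALSE, row.names = FALSE,
                       col.names = c("t", "heading_deg", "pitch_deg",
                                     "roll_deg", "valid"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) hods_error(sprintf("cannot write to '%s'", path), "hods_io_error")
  invisible(NULL)
}

#' Read an orientation series from CSV
#'
#' Inverse of [write_orientation_csv()].
#'
#' @param path CSV file written by [write_orientation_csv()].
#' @param fs sampling rate in Hz; inferred from the median time step when
#'   omitted.
#' @return an `orientation_series`.
#' @export
read_orientation_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("t", "heading_deg", "pitch_deg", "roll_deg", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) config_error(sprintf("missing column '%s'", miss[1]))
  if (is.null(fs)) {
    if (nrow(df) < 2) config_error("cannot infer fs from a single row")
    fs <- 1 / stats::median(diff(df$t))
  }
  orientation_series(heading = df$heading_deg, pitch = df$pitch_deg,
                     roll = df$roll_deg, fs = fs, t = df$t,
                     valid = as.logical(df$valid))
}
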