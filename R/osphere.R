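# The orientation sphere: heading is longitude, pitch is latitude, and
# every (heading, pitch) sample becomes a point on the unit sphere. All
# angular metrics (distances, speeds, turn magnitudes) are great-circle
# measures on this sphere.

#' Map (heading, pitch) onto the unit orientation sphere
#'
#' `(cos p cos h, cos p sin h, sin p)` with heading `h` and pitch `p` in
#' radians internally; the x axis points to heading 0 on the horizon and
#' the z axis to straight up (pitch +90).
#'
#' @param heading heading in degrees.
#' @param pitch pitch in degrees, [-90, 90].
#' @return N x 3 matrix of unit vectors (columns x, y, z).
#' @export
to_sphere <- function(heading, pitch) {
  h <- deg2rad(heading)
  p <- deg2rad(pitch)
  cbind(x = cos(p) * cos(h), y = cos(p) * sin(h), z = sin(p))
}

#' Recover (heading, pitch) from orientation-sphere points
#'
#' Inverse of [to_sphere()] away from the poles. At the poles heading is
#' degenerate and returned as 0.
#'
#' @param xyz N x 3 matrix of unit vectors.
#' @return list with `heading` and `pitch` in degrees.
#' @export
sphere_to_angles <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  list(heading = wrap360(rad2deg(atan2(xyz[, 2], xyz[, 1]))),
       pitch = rad2deg(asin(pmin(1, pmax(-1, xyz[, 3])))))
}

#' Great-circle angular distance between unit vectors
#'
#' `acos(clamp(a . b))` in degrees, in [0, 180]; symmetric. Row-wise when
#' both arguments are matrices.
#'
#' @param a,b unit 3-vectors or N x 3 matrices of them.
#' @return distances in degrees.
#' @export
angular_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- rowSums(a * b)
  rad2deg(acos(pmin(1, pmax(-1, d))))
}

#' Per-sample angular speed of an orientation series
#'
#' Default "sphere" mode: great-circle distance between consecutive
#' orientation-sphere points times the sampling rate, deg/s — the speed of
#' the full head orientation. "yaw" mode uses wrapped heading differences
#' only, the quantity colour-coded on body-relative plots. The first sample
#' and samples adjacent to invalid ones are NaN.
#'
#' @param series an `orientation_series`.
#' @param mode "sphere" (great-circle, default) or "yaw" (heading only).
#' @return numeric vector of speeds in deg/s, same length as the series.
#' @export
angular_speed <- function(series, mode = c("sphere", "yaw")) {
  mode <- match.arg(mode)
  n <- length(series$t)
  out <- rep(NaN, n)
  if (n < 2) return(out)
  if (mode == "sphere") {
    xyz <- to_sphere(series$heading, series$pitch)
    step <- angular_distance(xyz[-n, , drop = FALSE], xyz[-1, , drop = FALSE])
  } else {
    step <- abs(wrap180(diff(series$heading)))
  }
  out[-1] <- step * series$fs
  ok <- series$valid[-n] & series$valid[-1]
  out[-1][!ok] <- NaN
  out
}

#' Head yaw relative to the body
#'
#' Subtracts a synchronized body-tag heading from the head heading (wrapped
#' to [0, 360)), removing whole-animal rotation so that stereotyped head
#' behaviours stand out on the body-relative orientation sphere. Pitch is
#' copied from the head by default; set `subtract_pitch` to also remove
#' body pitch.
#'
#' @param head,body `orientation_series` of equal length and sampling.
#' @param subtract_pitch also subtract body pitch (clamped to [-90, 90]).
#' @return an `orientation_series` of body-relative orientation.
#' @export
body_relative <- function(head, body, subtract_pitch = FALSE) {
  if (length(head$t) != length(body$t))
    alignment_error(sprintf("length mismatch: head %d vs body %d samples",
                            length(head$t), length(body$t)))
  if (abs(head$fs - body$fs) > 1e-9)
    alignment_error("head and body series have different sampling rates")
  if (max(abs(head$t - body$t)) > 1e-6)
    alignment_error("head and body series are not time-aligned")
  valid <- head$valid & body$valid
  heading <- wrap360(head$heading - body$heading)
  pitch <- if (subtract_pitch)
    pmin(90, pmax(-90, head$pitch - body$pitch)) else head$pitch
  heading[!valid] <- NaN
  pitch[!valid] <- NaN
  orientation_series(heading = heading, pitch = pitch,
                     roll = ifelse(valid, head$roll, NaN),
                     fs = head$fs, t = head$t, valid = valid,
                     meta = head$meta)
}

#' Label head-behaviour states from angular speed
#'
#' Classifies each valid sample by its smoothed angular speed: below
#' `fix_speed` the head is holding still ("fixation"); between the two
#' thresholds it is moving slowly and continuously ("scan"); above
#' `scan_speed` it is reorienting rapidly between fixations ("transition").
#' Invalid samples are labelled "invalid". Runs shorter than `min_dur` are
#' merged into whichever neighbouring run lasts longer, suppressing
#' threshold chatter.
#'
#' @param series an `orientation_series`.
#' @param fix_speed fixation/scan boundary, deg/s (default 2).
#' @param scan_speed scan/transition boundary, deg/s (default 10).
#' @param min_dur minimum run duration in seconds (default 0.5).
#' @param speed_smooth baseline over which the smoothed angular speed is
#'   estimated, in seconds (default 0.5): speed at a sample is the
#'   great-circle distance between the orientations half a baseline before
#'   and after, divided by the elapsed time. Differencing consecutive
#'   samples would multiply orientation noise by the sampling rate; the
#'   longer baseline suppresses that by `1/(speed_smooth * fs)` while
#'   leaving steady motion unbiased.
#' @return object of class `state_labels`: per-sample `labels`, the
#'   per-sample `smoothed_speed` (deg/s) the labels were thresholded on,
#'   and a `segments` data frame (start, end, label, duration, mean_speed
#'   computed from the smoothed speed).
#' @export
label_states <- function(series, fix_speed = 2, scan_speed = 10,
                         min_dur = 0.5, speed_smooth = 0.5) {
  if (fix_speed >= scan_speed)
    parameter_error("fix_speed must be < scan_speed")
  if (min_dur * series$fs < 1)
    parameter_error("min_dur * fs must be >= 1")
  n <- length(series$t)
  h2 <- max(1L, round(speed_smooth * series$fs / 2))
  sm <- rep(NA_real_, n)
  r <- rle(series$valid)
  r_ends <- cumsum(r$lengths)
  r_starts <- r_ends - r$lengths + 1
  for (k in which(r$values)) {
    idx <- r_starts[k]:r_ends[k]
    m <- length(idx)
    xyz <- to_sphere(series$heading[idx], series$pitch[idx])
    j <- seq_len(m)
    a <- pmax(j - h2, 1L)
    b <- pmin(j + h2, m)
    d <- angular_distance(xyz[a, , drop = FALSE], xyz[b, , drop = FALSE])
    sm[idx] <- ifelse(b > a, d * series$fs / (b - a), 0)
  }
  lab <- rep("invalid", n)
  lab[series$valid & sm < fix_speed] <- "fixation"
  lab[series$valid & sm >= fix_speed & sm <= scan_speed] <- "scan"
  lab[series$valid & sm > scan_speed] <- "transition"

  # merge short runs within each valid stretch
  min_len <- round(min_dur * series$fs)
  merge_stretch <- function(labels) {
    repeat {
      r <- rle(labels)
      if (length(r$lengths) <= 1) break
      short <- which(r$lengths < min_len)
      if (!length(short)) break
      k <- short[which.min(r$lengths[short])]
      left <- if (k > 1) r$lengths[k - 1] else -1
      right <- if (k < length(r$lengths)) r$lengths[k + 1] else -1
      r$values[k] <- if (left >= right) r$values[k - 1] else r$values[k + 1]
      labels <- inverse.rle(r)
    }
    labels
  }
  vr <- rle(series$valid)
  v_ends <- cumsum(vr$lengths)
  v_starts <- v_ends - vr$lengths + 1
  for (k in which(vr$values)) {
    idx <- v_starts[k]:v_ends[k]
    lab[idx] <- merge_stretch(lab[idx])
  }

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts, end = ends, label = r$values,
                    stringsAsFactors = FALSE)
  seg$duration <- (seg$end - seg$start + 1) / series$fs
  seg$mean_speed <- vapply(seq_len(nrow(seg)), function(i) {
    v <- sm[seg$start[i]:seg$end[i]]
    if (all(!is.finite(v))) NaN else mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(labels = lab, segments = seg, smoothed_speed = sm,
                 thresholds = c(fix_speed = fix_speed,
                                scan_speed = scan_speed, min_dur = min_dur)),
            class = "state_labels")
}

#' @export
print.state_labels <- function(x, ...) {
  tab <- table(x$labels)
  cat("<state_labels>", paste(sprintf("%s: %d", names(tab), tab),
                              collapse = ", "), "\n")
  cat(sprintf("  %d segments\n", nrow(x$segments)))
  invisible(x)
}
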