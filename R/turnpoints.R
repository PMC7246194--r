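# 3D turning-point detection in (heading, pitch) series via spikes in the
# Squared Spherical Standard Deviation (SSSD).
#
# Each window of W+1 consecutive samples is mapped to unit vectors on the
# orientation sphere; the mean resultant length R of those vectors is 1
# when the head holds one orientation and shrinks as orientations
# disperse. s = ln(1/R^2) = -2 ln R is the spherical analogue of the
# squared circular standard deviation, so a head swinging through a turn
# while the window straddles it produces a spike in s. Spike midpoints are
# candidate turning points, kept only if the actual turn exceeds a
# threshold angle.

#' Squared spherical standard deviation over a sliding window
#'
#' For each index i with a full window of W+1 samples (i - W/2 ... i + W/2),
#' maps (heading, pitch) to unit vectors, averages them component-wise,
#' takes the mean resultant length R and sets `s_i = ln(1/R^2)`. `s_i = 0`
#' exactly when all window orientations coincide. Windows touching a
#' series edge, or containing a non-finite sample, are undefined and
#' absent from the trace.
#'
#' @param heading heading sequence in degrees.
#' @param pitch pitch sequence in degrees.
#' @param W window size in samples; must be a positive even integer < N.
#' @return object of class `sssd_trace`: `s` (values at `index`), `index`
#'   (1-based positions in the input), `W`, `global_mean` (mean of the
#'   defined values).
#' @export
sssd <- function(heading, pitch, W) {
  n <- length(heading)
  if (length(pitch) != n) parameter_error("heading and pitch lengths differ")
  if (W %% 2 != 0 || W < 2)
    parameter_error(sprintf(
      "W must be a positive even integer (the window spans W/2 samples either side); got %s", W))
  if (W >= n) parameter_error(sprintf("W (%d) must be < series length (%d)", W, n))
  h <- W / 2
  xyz <- to_sphere(heading, pitch)
  bad <- !is.finite(heading) | !is.finite(pitch)
  xyz[bad, ] <- 0
  cs <- apply(rbind(0, xyz), 2, cumsum)
  cb <- c(0, cumsum(bad))
  idx <- seq.int(h + 1, n - h)
  lo <- idx - h
  hi <- idx + h
  m <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (W + 1)
  R <- sqrt(rowSums(m^2))
  s <- pmax(-2 * log(R), 0)
  nbad <- cb[hi + 1] - cb[lo]
  keep <- nbad == 0
  structure(list(s = s[keep], index = idx[keep], W = as.integer(W),
                 n = n,
                 global_mean = if (any(keep)) mean(s[keep]) else NaN),
            class = "sssd_trace")
}

#' Construct an SSSD trace from given values
#'
#' Mostly useful for studying the spike semantics on constructed traces;
#' [sssd()] builds traces from data.
#'
#' @param s non-negative SSSD values.
#' @param index 1-based series indices the values sit at; defaults to
#'   consecutive positions starting at 1.
#' @param W window size the values notionally came from.
#' @return an `sssd_trace`.
#' @export
sssd_trace <- function(s, index = seq_along(s), W = 2L) {
  if (any(s < 0)) parameter_error("SSSD values must be >= 0")
  structure(list(s = as.numeric(s), index = as.integer(index),
                 W = as.integer(W), n = max(index, 0L) + W / 2,
                 global_mean = if (length(s)) mean(s) else NaN),
            class = "sssd_trace")
}

#' @export
print.sssd_trace <- function(x, ...) {
  cat(sprintf("<sssd_trace> W = %d, %d defined indices, global mean %.4g\n",
              x$W, length(x$s), x$global_mean))
  invisible(x)
}

#' Find SSSD spikes
#'
#' A spike is a maximal contiguous run of defined indices whose SSSD is
#' strictly above the trace's global mean. Runs cannot span undefined
#' gaps. A constant-zero trace yields no spikes (nothing exceeds the mean
#' strictly).
#'
#' @param trace an `sssd_trace`.
#' @return data frame with columns `start`, `end` (series indices),
#'   ordered.
#' @export
find_spikes <- function(trace) {
  if (!length(trace$s)) return(data.frame(start = integer(0), end = integer(0)))
  above <- trace$s > trace$global_mean
  # break runs across non-contiguous defined indices (NaN gaps)
  grp <- cumsum(c(1, diff(trace$index) != 1))
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    a <- above[sel]
    ix <- trace$index[sel]
    if (!any(a)) next
    r <- rle(a)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values))
      out[[length(out) + 1]] <- c(ix[starts[k]], ix[ends[k]])
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end")
  df[order(df$start), , drop = FALSE]
}

#' Midpoint of a spike interval
#'
#' `floor((start + end) / 2)`; even-length spikes break the tie downward.
#'
#' @param start,end interval bounds (indices), start <= end.
#' @return candidate turning-point index (vectorized).
#' @export
spike_midpoint <- function(start, end) {
  if (any(start > end)) parameter_error("start must be <= end")
  as.integer(floor((start + end) / 2))
}

#' Turn magnitude at a candidate index
#'
#' Great-circle angle between the normalized mean orientation vector over
#' the pre-window [i - W/2, i) and the post-window (i, i + W/2], the 3D
#' analogue of a before/after bearing change. Returns NA (candidate
#' rejected conservatively) when either window mean has norm < 1e-9, i.e.
#' the window is too dispersed to define a direction.
#'
#' @param series an `orientation_series`.
#' @param i candidate index; needs W/2 samples on each side.
#' @param W window size in samples (even).
#' @return turn angle in degrees, [0, 180], or NA.
#' @export
turn_angle <- function(series, i, W) {
  h <- W / 2
  n <- length(series$t)
  if (i - h < 1 || i + h > n)
    parameter_error("index too close to the series edge for this window")
  pre <- (i - h):(i - 1)
  post <- (i + 1):(i + h)
  mean_dir <- function(ix) {
    ok <- series$valid[ix] & is.finite(series$heading[ix])
    if (!any(ok)) return(NULL)
    m <- colMeans(to_sphere(series$heading[ix][ok], series$pitch[ix][ok]))
    nm <- sqrt(sum(m^2))
    if (nm < 1e-9) return(NULL)
    m / nm
  }
  a <- mean_dir(pre)
  b <- mean_dir(post)
  if (is.null(a) || is.null(b)) return(NA_real_)
  angular_distance(a, b)
}

#' Detect 3D turning points
#'
#' Full pipeline: SSSD trace -> spikes above the global mean -> spike
#' midpoints as candidates -> keep candidates whose turn magnitude is at
#' least `theta_thresh`. Defaults W = 40 samples (1 s at a 40 Hz tag) and
#' a 30 degree threshold. Candidates too close to the series edges to
#' evaluate a turn angle are dropped with a warning.
#'
#' @param series an `orientation_series`.
#' @param W sliding-window size in samples (even; default 40).
#' @param theta_thresh minimum turn magnitude in degrees (default 30).
#' @return object of class `turning_point_set`: `spikes` (data frame),
#'   `candidates` (indices), `accepted` (data frame with index, t,
#'   turn_angle), `theta_thresh`, `W` and the SSSD `trace`.
#' @export
detect_turning_points <- function(series, W = 40, theta_thresh = 30) {
  validate_orientation_series(series)
  trace <- sssd(series$heading, series$pitch, W)
  spikes <- find_spikes(trace)
  cand <- if (nrow(spikes)) spike_midpoint(spikes$start, spikes$end) else integer(0)
  h <- W / 2
  n <- length(series$t)
  edge <- cand - h < 1 | cand + h > n
  if (any(edge)) {
    warning(sprintf("dropped %d candidate(s) too close to the series edge",
                    sum(edge)), call. = FALSE)
    cand_eval <- cand[!edge]
  } else cand_eval <- cand
  ang <- vapply(cand_eval, function(i) {
    a <- turn_angle(series, i, W)
    if (is.na(a)) -Inf else a
  }, numeric(1))
  keep <- ang >= theta_thresh
  accepted <- data.frame(index = cand_eval[keep],
                         t = series$t[cand_eval[keep]],
                         turn_angle = ang[keep])
  structure(list(spikes = spikes, candidates = cand, accepted = accepted,
                 theta_thresh = theta_thresh, W = as.integer(W),
                 trace = trace),
            class = "turning_point_set")
}

#' @export
print.turning_point_set <- function(x, ...) {
  cat(sprintf(
    "<turning_point_set> W = %d, theta >= %g deg: %d spike(s), %d candidate(s), %d accepted\n",
    x$W, x$theta_thresh, nrow(x$spikes), length(x$candidates),
    nrow(x$accepted)))
  invisible(x)
}

#' Write a turning-point set to JSON
#'
#' @param x a `turning_point_set`.
#' @param path output file path.
#' @param include_trace include the full SSSD trace (default TRUE).
#' @export
write_turning_points <- function(x, path, include_trace = TRUE) {
  out <- list(W = x$W, theta_thresh = x$theta_thresh,
              spikes = x$spikes, candidates = x$candidates,
              accepted = x$accepted)
  if (include_trace)
    out$trace <- list(index = x$trace$index, s = x$trace$s,
                      global_mean = x$trace$global_mean)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(NULL)
}
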