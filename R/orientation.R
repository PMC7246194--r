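# Pitch, roll and tilt-compensated compass heading from tag sensors.
#
# The accelerometer senses the gravity reaction only when the head is
# quasi-static, so the acceleration channels are first smoothed with a
# running mean (~2 s); pitch follows from the smoothed surge component and
# roll from the heave/sway pair. The magnetometer triplet, levelled to the
# ground plane using those angles, then yields heading. Samples where the
# smoothed acceleration magnitude strays from 1 g (dynamic movement) or
# where pitch approaches +-90 deg (heading degenerate) are flagged invalid.

#' Orientation-derivation parameters
#'
#' @param smooth_window running-mean window for the acceleration channels,
#'   in seconds. Default 2 s: long enough to average out stride-scale
#'   dynamic acceleration, short enough to track deliberate head movement.
#' @param g_tolerance allowed deviation of the smoothed acceleration vector
#'   magnitude from 1 g before a sample is flagged invalid (default 0.15).
#' @param pitch_gimbal_deg |pitch| above which heading is degenerate and
#'   the sample is flagged invalid (default 85).
#' @param smooth_mag also smooth the magnetometer channels with the same
#'   window (off by default; the compass needs no smoothing when the
#'   acceleration angles are already smoothed).
#' @param declination_deg constant offset added to heading to convert
#'   magnetic to true bearings; default 0 (work in magnetic coordinates).
#' @return an object of class `orientation_params`.
#' @export
orientation_params <- function(smooth_window = 2, g_tolerance = 0.15,
                               pitch_gimbal_deg = 85, smooth_mag = FALSE,
                               declination_deg = 0) {
  if (smooth_window <= 0) parameter_error("smooth_window must be > 0")
  if (g_tolerance <= 0 || g_tolerance >= 1)
    parameter_error("g_tolerance must be in (0, 1)")
  if (pitch_gimbal_deg <= 0 || pitch_gimbal_deg > 90)
    parameter_error("pitch_gimbal_deg must be in (0, 90]")
  structure(list(smooth_window = smooth_window, g_tolerance = g_tolerance,
                 pitch_gimbal_deg = pitch_gimbal_deg, smooth_mag = smooth_mag,
                 declination_deg = declination_deg),
            class = "orientation_params")
}

#' Centered running mean with shrinking edges
#'
#' Box average over `round(window * fs)` samples, forced to an odd count
#' (+1 if even) so the window is symmetric and introduces no phase lag.
#' Near the edges the window shrinks to the available samples rather than
#' padding, so output length equals input length.
#'
#' @param x numeric signal.
#' @param window window length in seconds.
#' @param fs sampling rate in Hz.
#' @return smoothed signal, same length as `x`.
#' @export
running_mean <- function(x, window, fs) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  k <- round(window * fs)
  if (k < 1) parameter_error("window * fs must be >= 1")
  if (k %% 2 == 0) k <- k + 1
  h <- k %/% 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Pitch angle from the static acceleration vector
#'
#' `atan2(surge, sqrt(heave^2 + sway^2))` in degrees, range [-90, +90],
#' positive nose-up. The two-argument arctangent keeps the poles
#' (heave = sway = 0) defined. Sensitivity is greatest near the horizontal
#' and vanishes toward +-90 deg, the sine-law behaviour of a gravity-based
#' inclinometer.
#'
#' @param surge,heave,sway static (smoothed) acceleration in g; vectors.
#' @return pitch in degrees.
#' @export
pitch_from_acc <- function(surge, heave, sway) {
  if (any(surge == 0 & heave == 0 & sway == 0))
    hods_error("all-zero acceleration vector: orientation undefined",
               "hods_undefined_orientation")
  rad2deg(atan2(surge, sqrt(heave^2 + sway^2)))
}

#' Roll angle from the static acceleration vector
#'
#' `atan2(sway, heave)` in degrees, range (-180, +180]; 0 when the dorsal
#' (heave) axis points away from gravity, 180 when inverted.
#'
#' @param heave,sway static acceleration in g; vectors.
#' @return roll in degrees.
#' @export
roll_from_acc <- function(heave, sway) {
  if (any(heave == 0 & sway == 0))
    hods_error("heave and sway both zero (pitch is +-90): roll undefined",
               "hods_undefined_roll")
  r <- rad2deg(atan2(sway, heave))
  r[r <= -180] <- 180
  r
}

#' Tilt-compensated compass heading
#'
#' De-rotates the calibrated magnetometer vector by roll then pitch into
#' the ground plane and takes the compass bearing of its horizontal
#' component. With P = pitch and R = roll in radians and magnetometer
#' channels (mx, my, mz) along (surge, sway, heave):
#' \deqn{m_{north} = m_x \cos P - m_y \sin R \sin P - m_z \cos R \sin P}
#' \deqn{m_{east}  = m_y \cos R - m_z \sin R}
#' \deqn{heading = atan2(-m_{east}, m_{north})}
#' mapped to [0, 360), clockwise from magnetic North. The sign pattern
#' follows from the package's heave-up sensor frame and is validated
#' against the simulator forward model.
#'
#' @param pitch,roll angles in degrees (vectors).
#' @param mag N x 3 calibrated magnetometer matrix (or length-3 vector).
#' @return heading in degrees, [0, 360).
#' @export
tilt_compensated_heading <- function(pitch, roll, mag) {
  if (is.null(dim(mag))) mag <- matrix(mag, ncol = 3)
  if (any(rowSums(mag^2) == 0))
    hods_error("zero magnetometer vector: heading undefined",
               "hods_undefined_orientation")
  P <- deg2rad(pitch); R <- deg2rad(roll)
  m_north <- mag[, 1] * cos(P) - mag[, 2] * sin(R) * sin(P) -
    mag[, 3] * cos(R) * sin(P)
  m_east <- mag[, 2] * cos(R) - mag[, 3] * sin(R)
  wrap360(rad2deg(atan2(-m_east, m_north)))
}

#' Derive an orientation series from raw tag data
#'
#' The full pipeline: smooth the three acceleration channels; compute pitch
#' and roll from the smoothed values; calibrate the magnetometer; level it
#' and compute heading; flag samples invalid where the smoothed
#' acceleration magnitude deviates from 1 g beyond `g_tolerance` (dynamic
#' movement corrupts the gravity estimate) or |pitch| exceeds the gimbal
#' guard. Invalid samples keep NaN angles but stay in place so sampling
#' remains uniform.
#'
#' @param imu an `imu_series`.
#' @param cal a `mag_calibration`, or NULL to use the magnetometer as-is.
#' @param params an [orientation_params()].
#' @return an `orientation_series`.
#' @export
derive_orientation <- function(imu, cal = NULL,
                               params = orientation_params()) {
  validate_imu_series(imu)
  sm_surge <- running_mean(imu$acc_surge, params$smooth_window, imu$fs)
  sm_heave <- running_mean(imu$acc_heave, params$smooth_window, imu$fs)
  sm_sway <- running_mean(imu$acc_sway, params$smooth_window, imu$fs)
  gmag <- sqrt(sm_surge^2 + sm_heave^2 + sm_sway^2)
  pitch <- rad2deg(atan2(sm_surge, sqrt(sm_heave^2 + sm_sway^2)))
  roll <- rad2deg(atan2(sm_sway, sm_heave))
  roll[roll <= -180] <- 180
  mag <- cbind(imu$mag_x, imu$mag_y, imu$mag_z)
  if (isTRUE(params$smooth_mag))
    mag <- apply(mag, 2, running_mean, window = params$smooth_window,
                 fs = imu$fs)
  if (!is.null(cal)) mag <- apply_mag_calibration(mag, cal)
  heading <- wrap360(tilt_compensated_heading(pitch, roll, mag) +
                       params$declination_deg)
  valid <- abs(gmag - 1) <= params$g_tolerance &
    abs(pitch) <= params$pitch_gimbal_deg
  heading[!valid] <- NaN
  pitch[!valid] <- NaN
  roll[!valid] <- NaN
  orientation_series(heading = heading, pitch = pitch, roll = roll,
                     fs = imu$fs, t = imu$t, valid = valid,
                     meta = imu$meta)
}
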