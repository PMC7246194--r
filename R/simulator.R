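# Behaviour-script simulator: ground-truth orientation traces and
# synthetic raw sensor channels.
#
# A script is an ordered list of segments -- fixations (hold orientation),
# scans (move at constant angular speed), transitions (great-circle move
# to a target at a stated speed) and turns (instantaneous reorientation).
# build_orientation() renders the script into a ground-truth orientation
# series with per-sample labels and true turn indices; synthesize_imu()
# projects gravity and the geomagnetic field into the rotating sensor
# frame, applies magnetic distortion and adds seeded Gaussian noise. The
# round trip through calibration and orientation derivation is the
# package's convention oracle.

#' Script segment constructors
#'
#' `seg_fixation()` holds an orientation (jumping to `heading`/`pitch` if
#' given, otherwise holding the current one). `seg_scan()` moves at a
#' constant angular speed: `axis = "yaw"` sweeps heading at constant
#' pitch; `axis = "great_circle"` follows the great circle leaving the
#' current orientation at `bearing` degrees (0 = toward the zenith,
#' 90 = toward increasing heading). `seg_transition()` moves along the
#' great circle toward a target at a stated speed, holding the target on
#' arrival. `seg_turn()` is an instantaneous reorientation, recorded as a
#' true turning point; with `duration > 0` it then holds.
#'
#' @param duration segment length in seconds.
#' @param heading,pitch target orientation in degrees (NULL = keep current).
#' @param speed angular speed in deg/s.
#' @param axis scan mode, "yaw" or "great_circle".
#' @param bearing great-circle scan direction in degrees.
#' @return a segment list for [behavior_script()].
#' @name segments
NULL

#' @rdname segments
#' @export
seg_fixation <- function(duration, heading = NULL, pitch = NULL) {
  list(kind = "fixation", duration = duration, heading = heading,
       pitch = pitch)
}

#' @rdname segments
#' @export
seg_scan <- function(duration, speed, axis = c("yaw", "great_circle"),
                     bearing = 90) {
  list(kind = "scan", duration = duration, speed = speed,
       axis = match.arg(axis), bearing = bearing)
}

#' @rdname segments
#' @export
seg_transition <- function(heading, pitch, speed, duration = NULL) {
  list(kind = "transition", duration = duration, heading = heading,
       pitch = pitch, speed = speed)
}

#' @rdname segments
#' @export
seg_turn <- function(heading = NULL, pitch = NULL, duration = 0) {
  list(kind = "turn", duration = duration, heading = heading, pitch = pitch)
}

#' Assemble a behaviour script
#'
#' @param segments list of segments from the `seg_*` constructors.
#' @param fs sampling rate in Hz (default 40, a typical tag rate).
#' @param start_heading,start_pitch initial orientation in degrees.
#' @param seed integer seed attached to the script for downstream noise.
#' @param body_script optional nested `behavior_script` for a body tag.
#' @return an object of class `behavior_script`.
#' @export
behavior_script <- function(segments, fs = 40, start_heading = 0,
                            start_pitch = 0, seed = NULL,
                            body_script = NULL) {
  for (sg in segments) {
    if (!sg$kind %in% c("fixation", "scan", "transition", "turn"))
      script_error(sprintf("unknown segment kind '%s'", sg$kind))
    if (sg$kind != "turn" && !is.null(sg$duration) && sg$duration < 0)
      script_error("segment durations must be > 0")
    if (!is.null(sg$speed) && sg$speed < 0)
      script_error("scripted speeds must be >= 0")
  }
  structure(list(segments = segments, fs = fs,
                 start_heading = start_heading, start_pitch = start_pitch,
                 seed = seed, body_script = body_script),
            class = "behavior_script")
}

# Rodrigues rotation of unit vector u about unit axis k by angle a (rad).
rotate_about <- function(u, k, a) {
  u * cos(a) + pracma_cross(k, u) * sin(a) + k * sum(k * u) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Local tangent basis at orientation point u: toward zenith and toward
# increasing heading.
tangent_basis <- function(u) {
  zen <- c(0, 0, 1)
  east <- pracma_cross(zen, u)
  ne <- sqrt(sum(east^2))
  if (ne < 1e-12) east <- c(0, 1, 0) else east <- east / ne
  north <- pracma_cross(u, east)
  list(north = north / sqrt(sum(north^2)), east = east)
}

#' Render a behaviour script into a ground-truth orientation series
#'
#' Deterministic (no noise is involved at this stage). Each segment
#' contributes `round(duration * fs)` samples labelled with its kind; turn
#' segments with zero duration contribute none but record a true turning
#' point at the boundary sample (the first sample at the new
#' orientation).
#'
#' @param script a `behavior_script`.
#' @return list with `truth` (an `orientation_series`, roll 0), `labels`
#'   (per-sample character), and `turns` (true turn indices).
#' @export
build_orientation <- function(script) {
  fs <- script$fs
  h <- script$start_heading
  p <- script$start_pitch
  H <- numeric(0); P <- numeric(0); L <- character(0)
  turns <- integer(0)
  for (sg in script$segments) {
    if (!is.null(sg$heading) && sg$kind %in% c("fixation", "turn")) h <- sg$heading
    if (!is.null(sg$pitch) && sg$kind %in% c("fixation", "turn")) p <- sg$pitch
    if (sg$kind == "turn") {
      turns <- c(turns, length(H) + 1L)
      ns <- if (is.null(sg$duration)) 0L else round(sg$duration * fs)
      if (ns > 0) {
        H <- c(H, rep(h, ns)); P <- c(P, rep(p, ns))
        L <- c(L, rep("fixation", ns))
      }
      next
    }
    if (sg$kind == "fixation") {
      ns <- round(sg$duration * fs)
      H <- c(H, rep(h, ns)); P <- c(P, rep(p, ns))
      L <- c(L, rep("fixation", ns))
    } else if (sg$kind == "scan") {
      ns <- round(sg$duration * fs)
      tt <- seq_len(ns) / fs
      if (sg$axis == "yaw") {
        hh <- wrap360(h + sg$speed * tt)
        pp <- rep(p, ns)
      } else {
        u <- as.numeric(to_sphere(h, p))
        tb <- tangent_basis(u)
        b <- deg2rad(sg$bearing)
        d <- cos(b) * tb$north + sin(b) * tb$east
        k <- pracma_cross(u, d)
        k <- k / sqrt(sum(k^2))
        pts <- t(vapply(deg2rad(sg$speed) * tt,
                        function(a) rotate_about(u, k, a), numeric(3)))
        ang <- sphere_to_angles(pts)
        hh <- ang$heading; pp <- ang$pitch
      }
      H <- c(H, hh); P <- c(P, pp)
      L <- c(L, rep("scan", ns))
      if (ns > 0) { h <- hh[ns]; p <- pp[ns] }
    } else if (sg$kind == "transition") {
      u <- as.numeric(to_sphere(h, p))
      v <- as.numeric(to_sphere(sg$heading, sg$pitch))
      sep <- angular_distance(u, v)
      if (sg$speed <= 0 && sep > 1e-9)
        script_error("transition target unreachable at speed 0")
      dur <- sg$duration %||% (if (sg$speed > 0) sep / sg$speed else 0)
      ns <- round(dur * fs)
      tt <- seq_len(ns) / fs
      ang_t <- pmin(sg$speed * tt, sep)
      if (sep < 1e-12) {
        hh <- rep(h, ns); pp <- rep(p, ns)
      } else {
        k <- pracma_cross(u, v)
        nk <- sqrt(sum(k^2))
        if (nk < 1e-12) {
          # antipodal target: pick any axis orthogonal to u
          tb <- tangent_basis(u)
          k <- pracma_cross(u, tb$east)
        }
        k <- k / sqrt(sum(k^2))
        pts <- t(vapply(deg2rad(ang_t), function(a) rotate_about(u, k, a),
                        numeric(3)))
        ang <- sphere_to_angles(pts)
        hh <- ang$heading; pp <- ang$pitch
      }
      H <- c(H, hh); P <- c(P, pp)
      L <- c(L, rep("transition", ns))
      if (ns > 0) { h <- hh[ns]; p <- pp[ns] }
    }
  }
  n <- length(H)
  if (n == 0) script_error("script produced no samples")
  turns <- turns[turns <= n]
  list(truth = orientation_series(heading = H, pitch = P,
                                  roll = rep(0, n), fs = fs,
                                  meta = list(source = "simulator")),
       labels = L, turns = turns)
}

#' World model for sensor synthesis
#'
#' @param inclination_deg magnetic inclination (dip) in degrees, positive
#'   down; default 60, a mid-latitude value.
#' @param noise_acc accelerometer noise sd in g.
#' @param noise_mag magnetometer noise sd in field units.
#' @param hard_iron additive hard-iron offset (length 3).
#' @param soft_iron 3x3 distortion matrix applied to the true field
#'   (calibration recovers its inverse); must be invertible.
#' @return an object of class `world_model`.
#' @export
world_model <- function(inclination_deg = 60, noise_acc = 0, noise_mag = 0,
                        hard_iron = c(0, 0, 0), soft_iron = diag(3)) {
  if (abs(inclination_deg) >= 90)
    parameter_error("inclination must be in (-90, 90)")
  soft_iron <- matrix(as.numeric(soft_iron), 3, 3)
  if (abs(det(soft_iron)) < 1e-12)
    parameter_error("soft_iron must be invertible")
  structure(list(inclination_deg = inclination_deg, noise_acc = noise_acc,
                 noise_mag = noise_mag, hard_iron = as.numeric(hard_iron),
                 soft_iron = soft_iron),
            class = "world_model")
}

#' Synthesize raw IMU channels from a ground-truth orientation series
#'
#' Rotates the gravity reaction (1 g up) and the geomagnetic field (unit
#' horizontal-North component plus inclination) into the sensor frame with
#' the package's intrinsic Z-Y-X convention, applies the soft-iron matrix
#' and hard-iron offset to the magnetometer channels, and adds i.i.d.
#' Gaussian noise per channel. Identical seeds give identical output.
#'
#' @param truth an `orientation_series` (its roll channel is used; NaN
#'   roll is treated as 0).
#' @param world a [world_model()].
#' @param seed integer seed for the noise; NULL leaves the caller's RNG
#'   stream in charge.
#' @return an `imu_series`.
#' @export
synthesize_imu <- function(truth, world = world_model(), seed = NULL) {
  validate_orientation_series(truth)
  n <- length(truth$t)
  hd <- deg2rad(truth$heading)
  th <- deg2rad(truth$pitch)
  rl <- deg2rad(ifelse(is.finite(truth$roll), truth$roll, 0))
  # gravity reaction in the sensor frame (independent of heading)
  acc_surge <- sin(th)
  acc_sway <- sin(rl) * cos(th)
  acc_heave <- cos(rl) * cos(th)
  # geomagnetic field, world NED: (cos dip, 0, sin dip)
  dip <- deg2rad(world$inclination_deg)
  mwx <- cos(dip); mwz <- sin(dip)
  # intrinsic Z-Y-X de-rotation into the aero body frame, then map the
  # down-positive third axis onto the up-positive heave channel
  x1 <- cos(hd) * mwx
  y1 <- -sin(hd) * mwx
  z1 <- mwz
  x2 <- cos(th) * x1 - sin(th) * z1
  z2 <- sin(th) * x1 + cos(th) * z1
  y3 <- cos(rl) * y1 - sin(rl) * z2
  z3 <- sin(rl) * y1 + cos(rl) * z2
  mag <- cbind(x2, y3, -z3)
  mag <- t(world$soft_iron %*% t(mag) + world$hard_iron)
  with_seed(seed, {
    if (world$noise_acc > 0) {
      acc_surge <- acc_surge + stats::rnorm(n, 0, world$noise_acc)
      acc_heave <- acc_heave + stats::rnorm(n, 0, world$noise_acc)
      acc_sway <- acc_sway + stats::rnorm(n, 0, world$noise_acc)
    }
    if (world$noise_mag > 0)
      mag <- mag + matrix(stats::rnorm(3 * n, 0, world$noise_mag), n, 3)
    imu_series(acc_surge = acc_surge, acc_heave = acc_heave,
               acc_sway = acc_sway, mag_x = mag[, 1], mag_y = mag[, 2],
               mag_z = mag[, 3], fs = truth$fs, t = truth$t,
               meta = list(source = "simulator"))
  })
}

#' Read a behaviour script from YAML
#'
#' Expected keys: `fs`, optional `start_heading`/`start_pitch`/`seed`, and
#' `segments`, a list of maps each with a `kind` plus that kind's
#' parameters (see [segments]). An optional `body` key nests a second
#' script for a body tag.
#'
#' @param path YAML file.
#' @return a `behavior_script`.
#' @export
read_behavior_script <- function(path) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  parse_one <- function(y) {
    segs <- lapply(y$segments, function(sg) {
      kind <- sg$kind %||% script_error("segment missing 'kind'")
      switch(kind,
        fixation = seg_fixation(sg$duration, sg$heading, sg$pitch),
        scan = seg_scan(sg$duration, sg$speed, sg$axis %||% "yaw",
                        sg$bearing %||% 90),
        transition = seg_transition(sg$heading, sg$pitch, sg$speed,
                                    sg$duration),
        turn = seg_turn(sg$heading, sg$pitch, sg$duration %||% 0),
        script_error(sprintf("unknown segment kind '%s'", kind)))
    })
    behavior_script(segs, fs = y$fs %||% 40,
                    start_heading = y$start_heading %||% 0,
                    start_pitch = y$start_pitch %||% 0,
                    seed = y$seed,
                    body_script = if (!is.null(y$body)) parse_one(y$body))
  }
  parse_one(y)
}

#' Read a world model from YAML
#'
#' Keys mirror [world_model()] arguments; `soft_iron` may be a length-9
#' row-major vector or a length-3 diagonal.
#'
#' @param path YAML file.
#' @return a `world_model`.
#' @export
read_world_model <- function(path) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  si <- y$soft_iron
  soft <- if (is.null(si)) diag(3)
  else if (length(unlist(si)) == 3) diag(as.numeric(unlist(si)))
  else matrix(as.numeric(unlist(si)), 3, 3, byrow = TRUE)
  world_model(inclination_deg = y$inclination_deg %||% 60,
              noise_acc = y$noise_acc %||% 0,
              noise_mag = y$noise_mag %||% 0,
              hard_iron = as.numeric(unlist(y$hard_iron %||% c(0, 0, 0))),
              soft_iron = soft)
}
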