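# Hard/soft-iron magnetometer calibration by least-squares ellipsoid fitting.
#
# Raw magnetometer readings from a tag sit on an ellipsoid displaced from
# the origin: nearby permanently-magnetized material adds a constant offset
# (hard iron) and induced magnetization plus axis gain mismatch applies a
# linear distortion (soft iron). Calibration fits that ellipsoid and maps
# it back onto the unit sphere, after which only the field's direction --
# all that heading needs -- remains.

#' Construct a magnetometer calibration
#'
#' @param offset hard-iron bias, length-3 numeric (sensor units).
#' @param transform 3x3 soft-iron + scale correction matrix.
#' @param rms_residual RMS deviation of calibrated norms from 1.
#' @return an object of class `mag_calibration`.
#' @export
mag_calibration <- function(offset = c(0, 0, 0), transform = diag(3),
                            rms_residual = 0) {
  offset <- as.numeric(offset)
  transform <- matrix(as.numeric(transform), 3, 3)
  if (length(offset) != 3) calibration_error("offset must have length 3")
  if (abs(det(transform)) < 1e-12)
    calibration_error("transform must be invertible")
  structure(list(offset = offset, transform = transform,
                 rms_residual = as.numeric(rms_residual)),
            class = "mag_calibration")
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat("<mag_calibration>\n  offset:   ",
      paste(sprintf("%.6g", x$offset), collapse = ", "),
      sprintf("\n  rms residual: %.3g\n", x$rms_residual))
  invisible(x)
}

mag_matrix <- function(mag) {
  if (inherits(mag, "imu_series"))
    mag <- cbind(mag$mag_x, mag$mag_y, mag$mag_z)
  m <- as.matrix(mag)
  if (ncol(m) != 3) calibration_error("magnetometer data must be N x 3")
  m
}

#' Fit a hard/soft-iron calibration to magnetometer samples
#'
#' Least-squares ellipsoid fit: the general quadric through the samples is
#' solved (smallest singular vector of the design matrix), constrained to an
#' ellipsoid, and factored into a center (hard-iron offset) plus the
#' symmetric positive-definite square root of the shape matrix (soft-iron
#' correction). Calibrated vectors `transform %*% (m - offset)` are scaled
#' to unit mean norm; the unknown field magnitude carries no heading
#' information.
#'
#' The fit needs rotational coverage: samples concentrated on a plane or
#' line cannot pin down the ellipsoid. Coverage is checked as the condition
#' number of the centered data's principal axes (must be < 100).
#'
#' @param mag N x 3 matrix of magnetometer samples, or an `imu_series`.
#' @param diagonal_only if TRUE, fit only per-axis offsets and scales (no
#'   off-diagonal soft-iron terms).
#' @return a `mag_calibration`.
#' @export
fit_mag_calibration <- function(mag, diagonal_only = FALSE) {
  m <- mag_matrix(mag)
  n <- nrow(m)
  if (n < 9) calibration_error("need at least 9 samples to fit an ellipsoid")
  ctr <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] <= 0 || sv[1] / sv[3] >= 100)
    calibration_error(paste(
      "degenerate direction coverage (samples near-coplanar or collinear);",
      "record wider rotation coverage before calibrating"))
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  if (diagonal_only) {
    D <- cbind(x^2, y^2, z^2, 2 * x, 2 * y, 2 * z, 1)
  } else {
    D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z,
               2 * x, 2 * y, 2 * z, 1)
  }
  v <- svd(D)$v[, ncol(D)]
  if (diagonal_only) v <- c(v[1:3], 0, 0, 0, v[4:7])
  Q <- matrix(c(v[1], v[4], v[5],
                v[4], v[2], v[6],
                v[5], v[6], v[3]), 3, 3)
  q <- v[7:9]
  k <- v[10]
  if (sum(diag(Q)) < 0) { Q <- -Q; q <- -q; k <- -k }
  offset <- as.numeric(-solve(Q, q))
  scale_ <- as.numeric(t(offset) %*% Q %*% offset) - k
  if (scale_ <= 0) calibration_error("fit did not yield an ellipsoid")
  A <- Q / scale_
  eg <- eigen(A, symmetric = TRUE)
  if (any(eg$values <= 0))
    calibration_error("fit did not yield an ellipsoid (indefinite quadric)")
  T0 <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  cal0 <- T0 %*% (t(m) - offset)
  norms <- sqrt(colSums(cal0^2))
  transform <- T0 / mean(norms)
  resid <- sqrt(colSums((transform %*% (t(m) - offset))^2)) - 1
  mag_calibration(offset = offset, transform = transform,
                  rms_residual = sqrt(mean(resid^2)))
}

#' Apply a magnetometer calibration
#'
#' Replaces the magnetometer channels by `transform %*% (m - offset)`;
#' acceleration channels are untouched. Also accepts a bare N x 3 matrix.
#'
#' @param series an `imu_series` (or N x 3 magnetometer matrix).
#' @param cal a `mag_calibration`.
#' @return object of the same type with calibrated magnetometer values.
#' @export
apply_mag_calibration <- function(series, cal) {
  if (!inherits(cal, "mag_calibration")) calibration_error("cal is not a mag_calibration")
  m <- mag_matrix(series)
  out <- t(cal$transform %*% (t(m) - cal$offset))
  if (inherits(series, "imu_series")) {
    series$mag_x <- out[, 1]
    series$mag_y <- out[, 2]
    series$mag_z <- out[, 3]
    return(series)
  }
  out
}

#' Write a calibration to JSON
#'
#' @param cal a `mag_calibration`.
#' @param path output file path. Transform stored row-major.
#' @export
write_mag_calibration <- function(cal, path) {
  jsonlite::write_json(
    list(offset = cal$offset,
         transform = as.numeric(t(cal$transform)),
         rms_residual = cal$rms_residual),
    path, auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}

#' Read a calibration from JSON
#'
#' @param path file written by [write_mag_calibration()].
#' @return a `mag_calibration`.
#' @export
read_mag_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mag_calibration(offset = j$offset,
                  transform = matrix(j$transform, 3, 3, byrow = TRUE),
                  rms_residual = j$rms_residual)
}
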