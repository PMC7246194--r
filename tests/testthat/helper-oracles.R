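# Independent oracles and fixture generators, deliberately sharing no code
# with the package internals they check.

# Brute-force SSSD: explicit per-index loop, direct means.
brute_sssd <- function(heading, pitch, W) {
  h <- heading * pi / 180
  p <- pitch * pi / 180
  n <- length(h)
  half <- W / 2
  idx <- (half + 1):(n - half)
  s <- numeric(length(idx))
  for (k in seq_along(idx)) {
    w <- (idx[k] - half):(idx[k] + half)
    mx <- sum(cos(p[w]) * cos(h[w])) / length(w)
    my <- sum(cos(p[w]) * sin(h[w])) / length(w)
    mz <- sum(sin(p[w])) / length(w)
    s[k] <- log(1 / (mx^2 + my^2 + mz^2))
  }
  list(index = idx, s = s)
}

# 2D circular statistics: squared circular standard deviation of headings.
circular_sq_sd <- function(heading_deg) {
  h <- heading_deg * pi / 180
  rbar <- sqrt(mean(cos(h))^2 + mean(sin(h))^2)
  -2 * log(rbar)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Area-uniform random points on the unit sphere.
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Calibration-coverage script: yaw sweeps at a ladder of pitches, the tag
# equivalent of rolling a compass through all orientations.
coverage_script <- function(fs = 40) {
  segs <- list(seg_fixation(0.5, 0, 0))
  for (p in seq(-75, 75, by = 25))
    segs <- c(segs, list(seg_turn(heading = 0, pitch = p),
                         seg_scan(9, 40, "yaw")))
  behavior_script(segs, fs = fs)
}

# Random fixation-turn script with K true turns all >= min_turn degrees
# apart on the sphere, fixations >= 4 s.
turn_script <- function(K, min_turn = 50, fs = 40) {
  h <- stats::runif(1, 0, 360)
  p <- stats::runif(1, -30, 30)
  segs <- list(seg_fixation(stats::runif(1, 4, 6), h, p))
  for (k in seq_len(K)) {
    repeat {
      h2 <- stats::runif(1, 0, 360)
      p2 <- stats::runif(1, -30, 30)
      if (angular_distance(to_sphere(h, p), to_sphere(h2, p2)) >= min_turn)
        break
    }
    segs <- c(segs, list(seg_turn(h2, p2),
                         seg_fixation(stats::runif(1, 4, 6))))
    h <- h2; p <- p2
  }
  behavior_script(segs, fs = fs)
}
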