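# hods — head orientation analysis for accelerometer + magnetometer tags

Animals direct their senses by moving their heads, so a head-mounted tag
that records where the head points — an orientation-determining system
built from a tri-axial accelerometer and a tri-axial magnetometer — opens
a window onto what a free-ranging animal is attending to ("environmental
framing"), without cameras or eye tracking. `hods` implements the full
analysis stack for such tags:

* **Orientation derivation.** Pitch from the gravity vector,
  `pitch = atan2(surge, sqrt(heave² + sway²))`, and roll from
  `atan2(sway, heave)`, after a ~2 s running mean isolates the static
  (gravitational) component of acceleration; heading from the
  tilt-compensated compass, i.e. the magnetometer triplet levelled to the
  ground plane by pitch and roll. Samples where the smoothed acceleration
  magnitude strays from 1 g (dynamic movement) or pitch approaches ±90°
  are flagged invalid.
* **Magnetometer calibration.** Hard-iron offset and soft-iron distortion
  estimated by a least-squares ellipsoid fit and inverted so calibrated
  field vectors lie on the unit sphere.
* **The orientation sphere (O-sphere).** Each (heading, pitch) sample maps
  to the unit vector `(cos p cos h, cos p sin h, sin p)`. Facet-density
  "Dubai" histograms on a subdivided-icosahedron tessellation, great-circle
  angular speeds, body-relative yaw (head minus body heading), and
  fixation / scan / transition state labelling all operate on this sphere.
* **3D turning-point detection.** Over a sliding window of `W + 1` samples
  the squared spherical standard deviation `s = ln(1/R²)` is computed from
  the mean resultant length `R` of the window's unit vectors. Contiguous
  runs of `s` above its global mean are *spikes*; spike midpoints are
  candidate turning points, accepted when the angle between the pre- and
  post-window mean directions reaches a threshold (defaults `W = 40`
  samples — 1 s at a 40 Hz tag — and 30°).
* **A scripted simulator.** Behaviour scripts (fixations, scans,
  transitions, turns) are rendered to ground-truth orientation series and
  projected into raw sensor channels under a configurable world model
  (magnetic inclination, hard/soft iron, sensor noise), so every stage of
  the stack is testable without field data.

## Worked example

Simulate a head that fixates, scans at 5°/s, snaps 172° to a new target,
and fixates again — then recover everything from the synthetic raw
channels:

```r
library(hods)

script <- behavior_script(
  list(seg_fixation(5, heading = 40, pitch = -10),
       seg_scan(8, speed = 5, axis = "yaw"),
       seg_turn(heading = 250, pitch = 10),
       seg_fixation(5)),
  fs = 40, start_pitch = -10)
truth <- build_orientation(script)

world <- world_model(hard_iron = c(0.2, -0.1, 0.05),
                     soft_iron = diag(c(1.1, 0.9, 1.0)),
                     noise_acc = 0.005, noise_mag = 0.005)
imu <- synthesize_imu(truth$truth, world, seed = 7)

# calibrate on a wide-coverage rotation sequence recorded under the same world
cov <- build_orientation(behavior_script(c(
  list(seg_fixation(0.5, 0, 0)),
  unlist(lapply(seq(-75, 75, by = 25), function(p)
    list(seg_turn(heading = 0, pitch = p), seg_scan(9, 40, "yaw"))),
    recursive = FALSE)), fs = 40))
cal <- fit_mag_calibration(synthesize_imu(cov$truth, world, seed = 8))
cal
#> <mag_calibration>
#>   offset:    0.199886, -0.0999482, 0.0494095
#>   rms residual: 0.0049

orient <- derive_orientation(imu, cal)
orient
#> <orientation_series> 720 samples at 40 Hz, 720 valid (100.0%)

detect_turning_points(orient, W = 40, theta_thresh = 30)$accepted
#>   index      t turn_angle
#> 1   520 12.975   172.1361

label_states(orient)$segments
#>   start end      label duration mean_speed
#> 1     1 201   fixation    5.025   1.311892
#> 2   202 484       scan    7.075   4.910087
#> 3   485 560 transition    1.900 101.535620
#> 4   561 720   fixation    4.000 1.597532

dubai_histogram(orient)
#> <facet_histogram> icosphere_f8: 720 samples over 1280 facets (22 occupied)
```

The recovered hard-iron offset matches the injected `(0.2, -0.1, 0.05)` to
about 1e-4, the single accepted turning point sits one sample from the
scripted reorientation (index 521) with the correct 172° magnitude, the
scan segment's mean smoothed angular speed (4.9°/s) matches the scripted
5°/s, and the two fixations plus the scan arc occupy 22 sphere facets.
`render()` draws any series or histogram as O-sphere scatter/trajectory,
Dubai bars, time-radial or planar panels, writing the plotted numbers to a
JSON sidecar alongside the figure.

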