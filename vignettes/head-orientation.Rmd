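---
title: "Deriving and analysing animal head orientation from accelerometer and magnetometer tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analysing animal head orientation from accelerometer and magnetometer tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hods)
```

## The measurement model

A head-mounted tag senses two world-fixed reference vectors in its own
rotating frame: gravity, through a tri-axial accelerometer reading in g,
and the geomagnetic field, through a tri-axial magnetometer in arbitrary
units. `hods` fixes one frame convention everywhere: the world frame is
North-East-Down; the sensor frame is surge (longitudinal, forward), sway
(lateral, right) and heave (dorso-ventral, up when level); orientation is
the intrinsic Z-Y-X sequence heading → pitch → roll. A resting
accelerometer measures the gravity *reaction*, so a level tag reads
+1 g on heave.

With smoothed acceleration $(a_s, a_h, a_w)$ on (surge, heave, sway):

$$\text{pitch} = \operatorname{atan2}\!\big(a_s,\sqrt{a_h^2 + a_w^2}\big),
\qquad \text{roll} = \operatorname{atan2}(a_w, a_h).$$

The two-argument arctangent keeps the poles defined, and the pitch formula
is exact whatever the roll. Because the surge reading follows
$\sin(\text{pitch})$, the estimator is most sensitive near the horizontal
and loses resolution toward ±90° — the classic behaviour of a
gravity-based inclinometer, verified numerically in the test suite.

Heading uses the tilt-compensated compass: the calibrated magnetometer
vector $(m_x, m_y, m_z)$ is de-rotated by roll $R$ then pitch $P$ into the
ground plane,

$$m_N = m_x \cos P - m_y \sin R \sin P - m_z \cos R \sin P, \qquad
  m_E = m_y \cos R - m_z \sin R,$$

and $\text{heading} = \operatorname{atan2}(-m_E, m_N)$ mapped to
[0, 360), clockwise from magnetic North. The sign pattern follows from the
heave-up sensor frame; the package's own simulator, which rotates gravity
and field into the sensor frame with the same convention, is the oracle
that pins it down — the noise-free synthesize → calibrate → derive round
trip reproduces heading, pitch and roll to better than 1e-12 degrees, and
any sign error anywhere would break it. Headings are magnetic; a
declination offset is available but off by default.

### Why the acceleration is smoothed, and what validity means

The accelerometer senses gravity plus dynamic (movement) acceleration.
The package takes a centered running mean (default 2 s, forced to an odd
sample count so there is no phase lag; edges shrink rather than pad) of
all three acceleration channels before computing pitch and roll. Samples
where the smoothed vector magnitude deviates from 1 g by more than
`g_tolerance` (default 0.15) are flagged invalid — there the gravity
estimate is corrupted and pitch/roll would be fiction — as are samples
with |pitch| above the gimbal guard (default 85°), where heading is
degenerate. Invalid samples keep NaN angles but remain in the series so
downstream sliding windows see uniform sampling.

One consequence documented rather than hidden: during *fast pitch or roll
changes* the running mean averages acceleration across orientations, so
derived pitch lags and undershoots until the window clears the manoeuvre.
Heading-only motion is immune (gravity is invariant under yaw), which is
why the exact round-trip checks use scripts whose pitch is constant within
the smoothing window; large instantaneous reorientations are caught by
the 1-g check instead.

## Magnetometer calibration

Nearby magnetic material displaces and distorts the locus of raw
magnetometer readings from a sphere into an offset ellipsoid: a constant
(hard-iron) offset plus a linear (soft-iron and gain) distortion. The
package fits the general quadric to the samples by least squares (the
smallest singular vector of the design matrix), requires it to be an
ellipsoid, and factors it into a center — the hard-iron offset — and the
symmetric positive-definite square root of the shape matrix — the
correction transform. Calibrated vectors are rescaled to unit mean norm:
the field magnitude is unknowable from the tag and irrelevant to heading.
A `diagonal_only` switch restricts the fit to per-axis offset and scale.

The fit needs rotational coverage; data concentrated near a plane cannot
pin the ellipsoid down, so inputs whose centered principal-axis condition
number reaches 100 are refused with advice to record a wider rotation
sequence (in practice: roll the tag through all orientations, or fit on a
deployment segment with varied posture). Calibration is per input file;
whether tags need per-deployment or per-tag calibration is a field
decision the package does not take. Under measurement noise the algebraic
fit is rotation-equivariant only to first order; the residual varies by
parts in 10⁴ under rigid rotations of the input, which the tests bound.

## The orientation sphere

Heading as longitude and pitch as latitude place every sample at
$(\cos p \cos h, \cos p \sin h, \sin p)$ on the unit sphere. All angular
metrics are great-circle measures there: `angular_speed()` multiplies the
consecutive-sample arc by the sampling rate (with a yaw-only variant using
wrapped heading differences), and `body_relative()` subtracts a
synchronized body tag's heading from the head's to remove whole-animal
rotation, exposing stereotyped head movement. Body pitch subtraction is
opt-in; by default only yaw is body-relative.

### Dubai histograms

`dubai_histogram()` tessellates the sphere and counts samples per facet.
The default tessellation is a subdivided icosahedron (frequency 8 →
20·8² = 1,280 near-equal facets; the area ratio between the largest and
smallest facet is below 2.1) because a latitude–longitude grid
over-resolves the poles and would bias raw-count density maps; a lat/lon
grid is provided for comparability. Facets are assigned by greatest dot
product with the facet center, ties to the lowest index — deterministic
and order-independent. Counts always sum to the number of valid samples,
and facet areas (spherical-triangle areas by l'Huilier's formula) sum to
4π to machine precision. Bar height is the raw count by default with a
count-per-steradian option, since conventions differ on whether such
plots normalize by facet area.

### Behaviour states

`label_states()` classifies samples by smoothed angular speed: fixation
below `fix_speed`, scan between the thresholds, transition above
`scan_speed`. The defaults — 2 °/s, 10 °/s, minimum run 0.5 s — were
chosen once so that reported scanning speeds of grazing and walking
animals (≈ 4.6–5.2 °/s medians) sit inside the scan band; they are
configurable and should be revisited per species. The speed used for
thresholding is *not* the consecutive-sample speed: differencing adjacent
samples multiplies orientation noise by the sampling rate (0.5° of
heading noise at 40 Hz masquerades as tens of °/s). Instead the speed at
a sample is the great-circle distance between the orientations half a
baseline (`speed_smooth`, default 0.5 s) before and after, divided by the
elapsed time — unbiased for steady motion, and suppressing noise by the
baseline length. Runs shorter than `min_dur` are merged into the longer
neighbouring run to kill threshold chatter.

## Turning points: SSSD spikes

For a window of $W+1$ samples centered at $i$ (W even, so the window is
symmetric), let $R_i$ be the norm of the componentwise mean of the
window's unit vectors — the mean resultant length, 1 when all
orientations coincide and shrinking with dispersion. The squared
spherical standard deviation

$$s_i = \ln\!\frac{1}{R_i^2} = -2 \ln R_i$$

generalizes the squared circular standard deviation: with pitch
identically zero it reduces to $-2\ln \bar R$ of the headings alone,
which the tests verify against an independent 2D circular-statistics
routine to 1e-12. It is also invariant under any rigid rotation of the
orientation set, since $R$ depends only on the mean vector's length.

A head swinging through a turn while the window straddles it disperses
the window and spikes $s$. A *spike* is a maximal contiguous run of
defined indices with $s$ strictly above the trace's global mean (strict,
so a constant trace yields none; the mean is taken over defined indices
only). Its midpoint — floor of the interval average, a deterministic
tie-break for even spikes — is a candidate turning point, accepted when
the great-circle angle between the normalized mean orientations over the
pre-window $[i-W/2, i)$ and post-window $(i, i+W/2]$ reaches
`theta_thresh`. Windows containing invalid samples are undefined and
spikes cannot span them: fabricating variance across dropouts would
manufacture turns. Candidates too close to the series edge to evaluate
are dropped with a warning, and near-duplicate candidates are *not*
merged before thresholding — users of dense-turn data should be aware
multiple spikes can straddle one manoeuvre.

Defaults are a 40-sample window (1 s at the 40 Hz rate typical of these
tags) and a 30° threshold. On 100 seeded scripts of 1–5 fixation-to-
fixation turns of at least 50°, 4 s apart, with 2° heading noise, the
detector's sensitivity is 1.00 with 0 false alarms per script and a mean
localization error below 1 sample (recomputed by `scripts/acceptance.R`).

## The simulator: conditions, defaults, and what it omits

The simulator is first-class code, not a fixture: scripts of fixations,
constant-speed scans (pure-yaw or great-circle — both movement styles
occur in real deployments), constant-speed great-circle transitions and
instantaneous turns are rendered at a default 40 Hz, the rate of the
deployments the package's defaults target. The world model projects a
1 g gravity reaction and a unit magnetic field with 60° inclination (a
mid-latitude value; configurable) into the sensor frame, applies the
soft-iron matrix and hard-iron offset to the magnetometer channels, and
adds i.i.d. Gaussian noise per channel from an explicit seed — identical
seeds give bit-identical output, and no global RNG state is disturbed.
Test noise levels of 0.005 g and 0.005 field units reflect good tag
hardware; distortion test values (offset (0.2, −0.1, 0.05), diagonal
scales (1.1, 0.9, 1.0)) represent moderate iron contamination.

What it deliberately does not emulate: dynamic (locomotion) acceleration
beyond step-change fixtures for the 1-g validity check, centripetal
acceleration, sensor bias drift, temperature effects, and timestamp
jitter. Passing round-trip tests therefore demonstrate correctness of the
orientation mathematics and the detection pipeline under the stated noise
model — not robustness to gait-coupled dynamic acceleration, which real
head tags on running animals will see and which the validity flags only
coarsely excise.

## Numerical choices

* Angles are degrees at every interface; radians only inside formulas.
  Heading wraps to [0, 360) with the 360-boundary folded to 0; roll maps
  −180 to +180.
* The SSSD is computed from cumulative sums (exact to ~1e-13 against the
  direct loop) and clamped at 0 against floating-point undershoot;
  windowed means never mix across NaN gaps.
* Turn-angle evaluation rejects candidates whose pre- or post-window mean
  vector has norm below 1e-9 — a window so dispersed it defines no
  direction yields no turn rather than an arbitrary one.
* The ellipsoid fit normalizes the quadric by trace sign and refuses
  indefinite fits rather than returning complex square roots.
* CSV output is full-precision (`%.17g`), so write → read round trips are
  bit-exact; JSON artifacts are written without digit truncation.
* Problem sizes in the shipped checks (500-sample series, 200–1,000
  oracle replicates, 100 detection scripts, 100,000-point uniformity
  checks) were chosen to exercise every code path at tight tolerances
  while keeping a full run in seconds.

## Known limitations

* Sign conventions for roll and the compass de-rotation are internally
  consistent and oracle-validated, but other software may differ by a
  fixed reflection; compare a known rotation before mixing outputs.
* No gyroscope fusion: fast manoeuvres between accelerometer-quiet
  moments are invisible except through the validity flags, and heading
  during dynamic bursts is unrecoverable by design.
* No geo-referencing, declination model, or GPS time alignment; headings
  are magnetic and timestamps are seconds from series start.
* State-label thresholds are behavioural conventions, not estimates; the
  defaults bound plausible scanning speeds but any quantitative use on a
  new species should calibrate them against observation.
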