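Package: hods
Title: Head Orientation Analysis from Accelerometer and Magnetometer Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving animal head (and body) orientation from
    head-mounted tri-axial accelerometer and magnetometer tags: running-mean
    smoothing, pitch and roll from the gravity vector, hard/soft-iron
    magnetometer calibration by ellipsoid fitting, tilt-compensated compass
    heading, representation of orientations as points on the unit
    "orientation sphere" with tessellated facet-density (Dubai) histograms,
    body-relative yaw, angular-speed metrics and fixation/scan/transition
    state labelling, and detection of three-dimensional turning points via
    spikes in the squared spherical standard deviation (SSSD) over a sliding
    window. A seeded behaviour-script simulator synthesises raw sensor
    channels from ground-truth orientation traces so every stage can be
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
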