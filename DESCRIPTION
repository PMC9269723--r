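Package: equigait
Title: Detecting Training-Induced Locomotion Change in Horses from Body-Mounted IMUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen wearable inertial-sensor recordings of horse
    locomotion for changes induced by a training session. From synchronized
    accelerometer, gyroscope and orientation streams the package derives
    per-sensor kinematic channels (globally resolved vertical and horizontal
    acceleration, axis-to-vertical angles, and swing-twist limb angles),
    segments strides from the filtered sternum vertical acceleration,
    time-normalizes strides to 100 points, and computes stride-similarity
    indicators (Pearson correlation, root mean square deviation) together
    with movement-smoothness indicators (spectral arc length, log
    dimensionless jerk on acceleration). Indicators are screened for a
    before/after training effect with paired Wilcoxon signed-rank tests.
    A seeded synthetic multi-sensor gait generator with controllable
    fatigue-like perturbations makes the whole pipeline testable without
    real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
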