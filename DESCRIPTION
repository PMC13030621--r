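Package: gaitval
Title: Agreement, Reliability and Interpretability Analysis for
    Paired-System Gait Kinematics
Version: 0.1.0
Authors@R:
    person("gaitval", "maintainers", email = "gaitval@example.org",
           role = c("aut", "cre"))
Description: Evaluates a wearable inertial (IMU) gait-kinematics pipeline
    against an optoelectronic motion-capture reference. Provides a seeded
    synthetic cohort generator with a controlled between-system error
    structure, signal preparation (impact-based clock synchronization,
    coordinate-based and gyroscope-based gait event detection, gait cycle
    segmentation and 101-point time normalization), concurrent-validity
    metrics (RMSE, centered RMSE, Pearson correlation, difference in range
    of motion), variance-component intraclass correlation coefficients from
    a two-way mixed-effects model, and Gait Profile Score interpretability
    statistics with minimal-detectable-change reading.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
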