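Package: vialtrack
Title: Multi-Vial Fly Locomotion Tracking, Kinematic Descriptors and
    Lifespan Statistics
Version: 0.1.0
Authors@R:
    person("Vialtrack", "Developers", email = "vialtrack@example.org",
           role = c("aut", "cre"))
Description: Automated measurement of Drosophila locomotor behaviour in
    vertical culture vials filmed by a fixed camera. Provides a synthetic
    arena simulator with exported ground truth, background-subtraction fly
    detection with per-vial millimetre calibration, optimal-assignment
    centroid tracking, a panel of walking-kinematics descriptors with
    fly-count normalization (mean and maximum velocity, walking duration
    and distance, per-episode trajectory statistics, percent time in
    motion), and cohort-level lifespan statistics (Kaplan-Meier curves,
    log-rank tests, one-way ANOVA with Fisher's LSD post hoc). A command
    line interface wires the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
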