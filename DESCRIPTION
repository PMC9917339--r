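Package: afmrheo
Title: AFM Cell Microrheology: Hertz Fitting, Sweep-Frequency Analysis and
    Structural Damping Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) force curves
    and single-cell oscillatory microrheology. Reads and writes a plain-text
    force-curve container, segments curves into approach, dwell, modulation
    and retract phases, locates the contact point, fits Hertz contact models
    for spherical, parabolic and conical tips, demodulates stepped-frequency
    sweep segments into a complex modulus spectrum with hydrodynamic drag
    correction, and fits the power-law structural damping model
    E*(f) = E0 (1 + i eta) (f/f0)^alpha + i 2 pi f mu with
    eta = tan(pi alpha / 2). Includes cohort summaries with rank tests and
    Cohen's d effect sizes, drug-response time-course fate classification,
    and a synthetic force-curve generator with known ground truth so every
    stage of the pipeline can be verified by round-trip recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
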