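Package: semgforce
Title: Grip and 3D Push-Pull Force Estimation from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for continuous hand-force estimation from multichannel
    surface electromyography (sEMG), aimed at myoelectric prosthesis control.
    Provides sliding-window time-domain feature extraction (mean absolute
    value, mean square, zero crossings, Willison amplitude), a Generalized
    Regression Neural Network (Gaussian-kernel instance-based regression)
    mapping features to grip force or 3D push-pull force, k-fold
    cross-validated accuracy metrics (mean absolute error, root mean square
    error, Pearson correlation), one-way and main-effects two-way ANOVA with
    Tukey HSD homogeneous subsets for comparing features, and a synthetic
    sEMG + force session simulator emulating an 8-electrode, 10-bit, 1 kHz
    acquisition chain so the full pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
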