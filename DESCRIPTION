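Package: divnorm
Title: Divisive Normalization Models of Single-Trial Visuomotor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models of how the motor system updates reaching commands after a
    single trial of rotated visual feedback. Implements a population-coding
    model in which direction-tuned units respond to each visual cursor through
    Gaussian tuning with a max operation and are integrated under divisive
    normalization, together with a maximum-likelihood (cue-combination)
    competitor with signal-dependent observation noise. Provides closed-form
    single-cursor solutions, Monte-Carlo expected responses to cursor clouds,
    bounded multi-start nonlinear least-squares fitting, generators for the
    multi-cursor and cursor-cloud perturbation schedules, synthetic
    condition-level response data, and a fit-then-predict analysis pipeline
    with declining-rate statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
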