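Package: eismea
Title: Classification and Circuit Modeling of Microelectrode Array Impedance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing electrochemical impedance spectroscopy (EIS)
    measurements from chronically implanted microelectrode arrays. Implements a
    rule-based classifier that assigns each magnitude/phase spectrum to one of four
    failure-mode categories (hockey-stick, ski-slope, mixed, outlier), complex
    nonlinear least-squares fitting of a Randles equivalent circuit with a constant
    phase element, longitudinal analytics (1 kHz impedance tracking, phase-peak
    frequency, category population tables, group-wise aggregation), a Gaussian-kernel
    support-vector-machine benchmark of the classifier, and a synthetic cohort
    simulator that reproduces the longitudinal structure of a two-cohort implant
    study so that every stage is testable without access to animal data. Readers
    and writers are provided for a documented CSV dialect and an instrument-style
    tab-delimited export format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
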