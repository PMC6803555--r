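Package: tremordbs
Title: Tremor Quantification and Firing-Pattern Analysis for Harmaline/DBS Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for epoch-structured electrophysiology and
    force-plate sessions from the harmaline rodent tremor model with thalamic
    deep brain stimulation (DBS). Quantifies tremor with the Motion Power Ratio
    (8-12 Hz band power over 0-8 Hz band power of framed force-plate signals),
    classifies single units into four firing-pattern categories
    (oscillatory/irregular x burst/non-burst) from autocorrelogram spectra and
    interspike-interval burst statistics, and computes per-unit effect indices
    and pattern-proportion contingency tests across experimental epochs.
    Includes a synthetic-session generator (inhomogeneous Poisson spike trains
    and tremor-bearing force-plate traces) so every stage is testable without
    access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
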