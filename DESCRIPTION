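Package: combfork
Title: Replication Fork Analysis for Dual-Pulse DNA Combing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of DNA molecular combing experiments with
    sequential halogenated-nucleotide pulses (IdU then CldU). Provides a
    stochastic fiber simulator (origin firing, per-fork speeds, permanent fork
    stalling), a synthetic multi-channel fiber-image renderer with PSF blur and
    noise, a 1-D track detector recovering labeled segments from images, fork
    speed computation with the flanked/run-off rules, replication-unit pairing
    with symmetric/asymmetric/unidirectional classification, and two-condition
    comparison statistics (two-tailed t-test, Cohen's d, class-proportion
    chi-square), plus an end-to-end configurable pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
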