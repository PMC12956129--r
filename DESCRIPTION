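Package: tissueproc
Title: Programmable Solvent-Exchange Control for Automated Tissue Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hardware-agnostic control library for a low-cost automated tissue
    processor that carries biological specimens through graded ethanol series
    and other stepwise solvent-exchange protocols. Provides a JSON protocol
    store with the reference propidium-iodide staining routines built in,
    time-based peristaltic pump dosing from flow-rate calibration, two-stock
    dilution blending, compilation of routines into timed actuation schedules,
    a run-time engine with pause/abort, flush and self-test utilities, a
    mass-balance virtual device backend with noise and fault injection, and a
    staining-quality module that scores 1-D confocal intensity profiles by
    signal-to-noise ratio and compares processing methods with a Welch t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
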