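Package: rtrobust
Title: Robustness Assessment of Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to audit the dosimetric robustness of intensity-modulated
    photon treatment plans. Generates synthetic phantoms, structure sets and
    multi-phase arc plans, recomputes dose with a simplified analytic
    divergent-beam engine under random and systematic patient-setup
    uncertainties (rigid 6-DOF transforms) and systematic multi-leaf
    collimator miscalibrations, accumulates dose fraction-wise, and reports
    dose-volume endpoint differences (D98%, D2%, Dmean, D0.03cc) against the
    nominal scenario including worst-case aggregation per uncertainty group.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
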