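Package: pkafit
Title: Residue-Specific pKa Determination from NMR pH Titration Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for NMR pH titration experiments on proteins,
    from per-pH Sparky-dialect peak lists to residue-specific pKa values.
    Tracks assigned resonances across a titration series, converts peak
    trajectories into chemical shift perturbation (CSP) curves in Hz, fits
    a modified Henderson-Hasselbalch model by nonlinear least squares, and
    quantifies uncertainty with Monte-Carlo resampling and F-statistic
    profile confidence intervals. Downstream tools aggregate per-residue
    pKa evidence into best estimates, compute protonation fractions,
    charges and dominant protonation states at arbitrary pH, and edit PQR
    coordinate files to reflect experimental protonation states for
    Poisson-Boltzmann electrostatics. A synthetic titration-data generator
    with known ground truth supports validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
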