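Package: ctffr
Title: Reduced-Order Coronary Hemodynamics, CT-FFR Calibration, and
    Virtual Diagnostic Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes fractional flow reserve (FFR) on branching coronary
    vessel trees with a reduced-order (1-D network) steady-flow model:
    Poiseuille viscous losses, post-stenotic expansion losses, and
    diameter-scaled outlet resistances under hyperemia.  Boundary-condition
    parameters are calibrated against invasively measured FFR by bounded
    multi-start derivative-free minimization of the mean squared error, then
    frozen and applied prospectively.  A seeded virtual-cohort generator
    builds diseased vessel trees with CTA-style stenosis readings and plaque
    covariates, and an evaluation layer reproduces a diagnostic-accuracy
    trial analysis: confusion-matrix metrics with Wilson intervals,
    rank-based AUC with DeLong variance, Bland-Altman agreement, per-FFR-bin
    accuracy, gray-zone stratification, group comparisons, and univariate
    logistic risk-factor screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
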