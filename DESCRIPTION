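Package: glucalib
Title: Sparse Bayesian Calibration and Agreement Analysis for Glucose Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates raw biosensor output (ultrasonic receiver voltage
    paired with titrated glucose additions) to blood glucose concentration
    using a from-scratch relevance vector machine (sparse Bayesian kernel
    regression with type-II maximum-likelihood hyperparameter estimation),
    and evaluates the resulting meter against a reference meter with the
    standard clinical agreement toolkit: Clarke, Parkes (consensus) and
    surveillance error grids, normalized correlation, bias/MARD statistics,
    modified Bland-Altman limits of agreement, and glycemic-class summaries.
    Includes a seeded synthetic-data generator that emulates the statistical
    structure of an in-vitro glucose titration experiment, and an end-to-end
    pipeline from generation through calibration to the agreement report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
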