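Package: fcstates
Title: Three-Condition Functional Connectome Edge-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds resting-state functional connectomes from ROI time
    series (Pearson correlation, Fisher z transform, positive-weight
    binarization), computes binary graph metrics (degree, clustering
    coefficient, local efficiency), and classifies every edge and node
    metric into a disorder/cured/activated/unchanged state across a
    control group and a patient group measured before and after an
    intervention. Includes delta-score clinical correlation analysis,
    RBF support-vector verification of connectivity biomarkers with ROC
    curves, and a synthetic paired-cohort generator with planted edge
    effects and clinical couplings so the whole pipeline can be
    exercised and power-tested without access to scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
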