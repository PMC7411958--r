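Package: qsrrmoo
Title: Elution-Order Prediction by QSRR with Multi-Objective Coefficient Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative structure-retention relationship (QSRR) modelling of
    gradient reversed-phase HPLC retention with explicit optimization of the
    predicted elution order. Linear retention models are fit by multiple
    linear regression and their coefficients re-optimized by an elitist
    non-dominated-sorting genetic algorithm against two objectives, the
    relative root-mean-square error of retention time and of elution order,
    yielding a Pareto front with knee-point detection and user-bounded
    solution selection. Includes Kennard-Stone train/test splitting,
    Williams-plot applicability-domain diagnostics, sum-of-ranking-differences
    (SRD) column comparison with comparison-of-ranks-of-random-numbers (CRNN)
    validation, and a synthetic-data generator emulating descriptor/retention
    tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
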