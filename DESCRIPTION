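Package: uromet
Title: Longitudinal Urine NMR Metabolic Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for two-group longitudinal metabolic profiling of 1D 1H
    NMR urine spectra: spectral bucketing and total-intensity normalization,
    Bonferroni-controlled univariate screening with Mann-Whitney AUC and fold
    changes, two-class PLS-DA fitted by NIPALS with cross-validated R2Y/Q2 and
    VIP scores, a Mahalanobis-distance F-test for score-plot cluster
    separation, hypergeometric over-representation analysis of affected
    metabolite sets, and a synthetic urine-NMR cohort generator with known
    ground truth for power and error-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pheatmap,
    withr
Config/testthat/edition: 3
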