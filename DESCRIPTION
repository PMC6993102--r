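Package: maldimarkers
Title: Random-Forest Biomarker Discovery for MALDI-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of candidate metabolite biomarkers from binary-class
    MALDI mass-spectral feature tables. Implements per-vector maximum
    normalization, elimination of linearly dependent m/z channels by
    Gauss-Jordan elimination with max-median group representatives,
    patient-grouped train/validation/test partitioning, Random-Forest
    tree-count grid search and iterative importance ranking optimised for
    f1-score, an empirical-CDF marker criterion with a configurable
    dominance threshold, ppm-accurate adduct annotation against a local
    compound table, and a synthetic-cohort generator with planted markers
    and planted linearly dependent channel groups for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    ranger,
    e1071,
    kernlab,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
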