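Package: deltarad
Title: Delta-Radiomics Feature Screening for MR-Guided Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a 53-feature radiomics panel (first-order statistics,
    3D morphology, per-slice box-counting fractal dimension, and grey-level
    run-length texture) from serial MR lesion volumes with binary masks,
    forms baseline-normalised delta ratios at cumulative-dose levels, and
    screens absolute and delta features against a binary clinical
    complete-response outcome with an exact Wilcoxon-Mann-Whitney test.
    Includes a longitudinal phantom-cohort simulator and machine-readable
    in-study reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
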