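Package: nigraquant
Title: Quantitative Iron-Neuromelanin MRI Analysis of the Substantia Nigra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of neuromelanin-sensitive,
    quantitative susceptibility mapping (QSM) and susceptibility map-weighted
    (SMWI) midbrain MRI in Parkinson's disease. Extracts the standard set of
    substantia-nigra mask parameters (mean signal / susceptibility, percentile
    contrast range, mask areas before and after signal or susceptibility
    thresholding), combines the best-discriminating parameters into a composite
    neuromelanin-iron marker, and provides the accompanying statistical layer:
    pooled-SD effect sizes, ROC analysis with DeLong confidence intervals and
    Youden operating points, Bonferroni-corrected Spearman correlation tables
    against clinical scores, intraclass correlation, and Fleiss/Cohen kappa
    rater agreement. A synthetic midbrain phantom generator (feature tables or
    full NIfTI volumes with masks) reproduces published cohort summary
    statistics so the whole pipeline can be exercised and tested without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
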