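Package: varprox
Title: Proxy-Label Training Sets and Deleteriousness Models from Standing Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds proxy-benign and proxy-deleterious variant training sets
    from frequency-stratified population variation, with substitution-spectrum
    matched subsampling to control label leakage. Provides a CADD-style feature
    pipeline (imputation, one-hot encoding of categorical annotations, feature
    crosses, feature-group exclusion, z-normalization), iterative L2-regularized
    logistic regression with per-iteration snapshots and validation-based
    iteration selection, rank-based PHRED scaling of scores, ranking metrics
    with consequence-stratified evaluation, ClinVar-style and MPRA-style
    benchmark construction, and a seeded synthetic-data generator so the full
    pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
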