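Package: phenosev
Title: Phenotype-Level Severity Measures and Classification from EHR Event Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Computes phenotype-level (not patient-level) severity from
    OMOP-style electronic health record event tables: five severity
    measures per phenotype (condition treatment time, comorbidity,
    medication and procedure burden, and procedure cost from a fee
    schedule), a proportional severity index combining them, and a
    mild/severe classification based on the proximity matrix of an
    unsupervised random forest anchored on a curated reference standard.
    Includes evaluation statistics (sensitivity/specificity, Cohen's and
    Fleiss' kappa, Wilcoxon rank-sum contrasts, per-class error curves)
    and a synthetic EHR cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Matrix,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
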