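Package: organotropism
Title: Predicting Organotropic Metastasis from Primary Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-learning architecture for predicting site-specific
    (organotropic) metastasis from bulk tumor transcriptomes. Provides
    clinical-annotation harmonization into per-(cancer, site) progression
    labels, SMOTE minority oversampling with an 80%-of-majority stopping
    rule, blockwise consensus feature selection with five selectors and
    support voting, tree-ensemble tumor-type and per-site classifiers with
    leakage-safe evaluation, Fisher's exact feature-recapture tests, GO
    biological-process overrepresentation with a multiplicity-weighted
    simulation null, semantic-similarity clustering of enriched terms, and
    a synthetic-cohort generator with planted tropism signatures for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    ranger,
    xgboost,
    igraph,
    jsonlite,
    withr,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
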