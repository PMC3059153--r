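Package: unifyexpr
Title: Unified Gene Expression Measures Across Platforms by Single-Factor
    Maximum-Likelihood Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates concomitant gene expression measurements of the same
    samples from multiple microarray platforms into one unified expression
    measure per gene. Fits a single-factor maximum-likelihood factor
    analysis model per gene (EM algorithm, unit-diagonal correlation
    parameterization) at the gene-summary or pooled probe level, estimates
    the latent expression by Thomson regression factor scores, detects
    Heywood cases and other model-fit problems, computes bootstrap standard
    errors for the loadings, simulates data from the model to compare
    factor-based integration with simple averaging, and provides
    precision/accuracy evaluation statistics (pooled replicate variance,
    squared distance to a reference technology, fold changes, ROC curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pROC,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
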