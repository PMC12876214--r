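Package: codysbiosis
Title: Cross-Kingdom Microbiome Networks and Co-Dysbiosis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising cross-kingdom (bacterial-fungal)
    interaction structure in case-control microbiome cohorts. Implements
    Spearman correlation network inference with Benjamini-Hochberg false
    discovery rate thresholding, network topology summaries including the
    co-dysbiosis index (positivity fraction of significant edges), alpha and
    beta diversity with PERMANOVA and Procrustes/PROTEST permutation tests,
    LEfSe-style linear discriminant effect-size biomarker scoring,
    cross-validated random-forest discrimination, reporter-score pathway
    aggregation of KEGG Orthology group differences, and a Gaussian-copula
    synthetic cohort generator with planted correlation structure, planted
    group differences, zero inflation and immunoglobulin E covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
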