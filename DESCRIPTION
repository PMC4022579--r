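Package: crossomix
Title: Cross-Platform Toxicogenomics Classification of Hepatocarcinogens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates mRNA, miRNA and protein log2 fold-change profiles from
    short-term rodent toxicity studies into machine-learning models that
    discriminate genotoxic carcinogens, non-genotoxic carcinogens and
    non-hepatocarcinogens. Provides molecular-interaction features (products of
    rescaled cross-platform log-ratios), per-sample pathway-enrichment features
    (hypergeometric overrepresentation scores), SVM-based recursive feature
    elimination with consensus signatures, nested compound-level
    cross-validation with five classifiers, confidence-scored classification of
    compounds of undefined carcinogenic class, and a seeded synthetic-data
    generator emulating the three-platform study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    randomForest
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
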