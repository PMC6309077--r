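Package: sensmap
Title: Cross-Study Transfer Learning for Drug Sensitivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfer-learning tools for predicting anti-cancer drug
    sensitivity (AUC) in a data-poor target study of cancer cell lines using
    a data-rich source study profiled over the same cell lines and genes.
    Implements two families of methods: (1) latent-variable cost-optimization
    predictors (Latent Regression Prediction, Latent-Latent Prediction and
    their combination), which model both studies' sensitivity vectors as
    affine functions of a shared latent signal recovered by a constrained
    ratio-cost optimization, and (2) Mapped Prediction, a domain-transfer
    pipeline built on gene-wise first-order and drug-wise second-order
    polynomial cross-study maps around a bias-corrected random-forest
    regressor. Includes RReliefF feature ranking with cross-study
    intersection, baseline predictors, a fold-based benchmark protocol,
    and a synthetic paired-study generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
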