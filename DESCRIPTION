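Package: physep
Title: Split-Half Reliability and Residual Separability for a Physical-Prediction Task Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for individual-differences analysis of a five-task
    behavioral battery pairing an unstable-towers physical-prediction task
    with spatial reasoning (paper folding, mental rotation) and complex-span
    working memory (spatial, verbal) measures. Implements trial-level
    scoring with task-specific chance floors, secondary-task participant
    screening, stratified split-half reliability with Spearman-Brown
    correction, permutation-based correlation inference, nested OLS model
    comparison via AIC evidence ratios and F tests, and the split-half
    residual-reliability procedure that tests whether physical-prediction
    ability is separable from spatial and working-memory abilities. Includes
    a latent-factor synthetic cohort generator (guessing-floor logistic
    response model) with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
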