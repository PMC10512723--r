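Package: amyvoice
Title: Predicting CSF Amyloid Status from Acoustic Speech Features
Version: 0.1.0
Authors@R: person("amyvoice", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for classifying cerebrospinal-fluid amyloid
    status in mild cognitive impairment from the 88 eGeMAPS v02 acoustic
    functionals of a spontaneous-speech recording. Provides group-contrast
    statistics (pooled-variance t, continuity-corrected chi-square,
    covariate-adjusted logistic models), wrapper feature selection by
    variable-length particle swarm optimization with a KNN fitness, a model
    zoo (elastic net, random forest, PCA-preceded classifiers), plain and
    bootstrap-nested leave-one-out cross-validation with percentile
    confidence intervals, and exact Shapley attributions of held-out
    predictions. A synthetic cohort generator with planted group effects
    makes every stage testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
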