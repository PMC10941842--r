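Package: fuzzyconn
Title: Explainable Fuzzy Clustering of Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for fuzzy-state analysis of dynamic functional network
    connectivity (dFNC) from component time series: tapered sliding-window
    Pearson connectivity extraction, fuzzy c-means state identification with
    fuzzy-partition-coefficient model selection, perturbation-based
    explainability (percent cluster switching and membership
    Kullback-Leibler divergence, globally and per sample), fuzzy-state
    dynamical and stability feature extraction, two-group inference with
    per-family false-discovery-rate control, elastic-net logistic
    classification with nested cross-validation, and covariate-adjusted
    symptom-severity regression. Includes a synthetic-data generator that
    plants connectivity states, membership trajectories, and group effects
    so the whole pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    pROC,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
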