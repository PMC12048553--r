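Package: csnn
Title: Chemical Space Neural Networks for Sparse Drug-Target Interaction Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds thresholded all-vs-all Tanimoto chemical space networks over
    compound libraries and exploits their network homophily to annotate sparse
    drug-target interaction matrices. Provides training-free labels-as-features
    (LaF) predictions of bioactivity classes and binding affinities from chemical
    neighbourhoods, edge-attributed neighbourhood neural networks for single- and
    multi-receptor prediction with masked cross-entropy, compound-to-prediction
    baselines with and without neighbourhood features, scaffold-aware data
    splitting with leakage filtering, classification/regression/enrichment
    metrics, receptor distance statistics, and Z-score hit calling for
    high-throughput screens. A synthetic homophilous chemical-space generator
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    MASS,
    withr,
    jsonlite,
    randomForest,
    nnet,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
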