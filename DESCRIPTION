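Package: fusedda
Title: Drug-Disease Association Prediction via Similarity Network Fusion and a Deep Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease associations for drug repurposing by
    integrating multiple binary feature views. Per-view cosine similarity
    matrices for drugs (chemical structure, side effects, protein targets)
    and diseases (phenotype, protein targets) are fused by similarity
    network fusion (iterative cross-diffusion with KNN local kernels) into
    unified drug and disease similarity matrices. Each (drug, disease) pair
    is represented by the concatenation of its fused similarity rows,
    classes are balanced with SMOTE inside training folds, and a deep
    feed-forward network with sigmoid output scores each pair. Evaluation
    covers confusion metrics, ROC/PR areas, repeated k-fold
    cross-validation, and a leave-one-association-out new-drug ranking
    experiment. A seeded synthetic generator with planted group structure
    makes the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
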