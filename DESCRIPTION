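Package: topofuse
Title: Topological Feature Fusion for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions by combining persistent-homology
    features of drug molecular images and protein contact maps with sequence
    embeddings. Implements sublevel-set cubical filtrations and H0/H1
    persistence diagrams for raster images, Betti-curve and persistence-
    landscape vectorization into fixed-length topological feature vectors, a
    learnable sigmoid-gated fusion of topological and sequence embeddings, and
    a two-layer heterogeneous mean-aggregation graph neural network link
    classifier trained with binary cross-entropy, Adam, and early stopping.
    Includes random and cold (unseen-drug/unseen-target) evaluation splits,
    AUROC/AUPRC/sensitivity/specificity reporting over seeded repeat runs, and
    synthetic generators for images with planted topology and interaction
    datasets with planted latent structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
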