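Package: toxtriad
Title: Heterogeneous Descriptor Integration for Acute Toxicity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of rat acute oral toxicity (pLD50) from three
    heterogeneous descriptor domains: 2D chemical descriptors, in-silico
    protein-target interaction-likelihood scores from a Laplacian-modified
    naive Bayes multi-target model, and quantitative high-throughput-screening
    (qHTS) cell-viability dose-response descriptors.  Implements fold-internal
    preprocessing (near-zero-variance and greedy correlation filtering with
    per-domain calibrated cutoffs, range scaling, chemical-space downsampling),
    repeated class-stratified cross-validation of random forests over all
    descriptor-domain combinations with shared splits, y-randomization
    robustness testing, and an evaluation suite covering paired performance
    comparisons, applicability-domain profiles, Mantel tests of domain
    independence, variable-importance aggregation and nearest-neighbour
    target-score contrasts.  A synthetic-cohort generator with known latent
    toxicity mechanisms makes the whole workflow testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
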