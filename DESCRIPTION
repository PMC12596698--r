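Package: psofusion
Title: Particle-Swarm-Optimized Fusion of Heterogeneous Pairwise Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise prediction (drug-drug interaction, drug-disease
    association and similar tasks) from heterogeneous per-entity binary
    feature matrices. Each feature type is standardized into a Jaccard
    similarity profile, every feature-type pair gets a dedicated feed-forward
    network, all networks are refined jointly by particle swarm optimization
    over their flattened weights, and the frozen base-model outputs are fused
    by a stacking network (with voting, averaging and weighted-sum
    alternatives). Includes a planted-signal synthetic task generator,
    seeded data splits, the usual six classification metrics, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
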