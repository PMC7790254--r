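Package: persotypes
Title: Replicable Big Five Personality Prototypes by Multi-Algorithm Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-centered derivation of Big Five personality prototypes
    from short-inventory item data. Scores 15-item trait inventories, applies
    missingness and intradimensional-variance exclusion rules, clusters trait
    z-profiles with Ward-initialized k-means, Gaussian-mixture latent profile
    analysis, and normalized spectral clustering, and selects the number of
    clusters by a split-half replication protocol: resampled half-sample
    clustering, cross-half reclassification with one-vs-rest support vector
    machines, external agreement criteria (Cohen's kappa, Rand, adjusted
    Rand) with a kappa gate, a twelve-index internal/external validity
    battery (C-index, Baker-Hubert Gamma, G+, generalized Dunn index GDI31,
    point-biserial, silhouette, S_Dbw, AIC, BIC), and vote-count model
    selection. Winning clusters are labeled against literature reference
    prototypes by profile-similarity D, and prototype similarities are
    correlated with criterion variables for predictive validity. A synthetic
    panel-data generator with planted prototype structure, careless
    responders, and missingness makes every stage testable without
    restricted-access survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    mclust,
    clue,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
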