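Package: atrophynet
Title: Surface-Based Morphometry and Atrophy Network Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Vertex-wise surface-based morphometry (general linear models
    with nuisance covariates, iterative surface smoothing, cluster
    extraction with Monte Carlo cluster-wise correction, false discovery
    rate control) and atrophy network mapping against a normative
    functional connectome (weighted-degree centrality similarity and
    disease-epicenter identification with spin-permutation inference).
    Includes a synthetic-data generator producing spherical cortical
    meshes, parcellation atlases, cohorts with planted severity-volume
    effects, and connectomes with planted epicenters, so the full
    pipeline is testable without any imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
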