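Package: HEPT
Title: Essential Protein Prediction with a Tensor-Extended HITS Random Walk
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts essential proteins from a protein-protein interaction
    network integrated with protein domain annotations, Gene Ontology
    annotations, orthology counts and subcellular localization. A three-slice
    relation tensor (co-neighbor, co-domain, co-annotation) is built over the
    proteins and ranked by a HITS-style power iteration extended to tensors,
    in which authority, hub and edge-type importance scores reinforce each
    other and the authority update is personalized by a restart vector
    derived from orthology conservation and subcellular localization.
    Includes evaluation utilities (top-K counts, precision-recall curves,
    jackknife cumulative-count curves, ranking overlap analysis, a degree
    centrality baseline) and a synthetic data generator with planted
    essential proteins for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, SystemsBiology, Network
RoxygenNote: 7.3.3
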