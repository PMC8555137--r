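Package: anchornet
Title: Anchored Protein Subnetwork Reconstruction with Ensemble
    Confidence and Machine-Learning Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs anchored protein subnetworks from weighted
    protein-protein interaction networks: given anchor proteins thought to
    mediate a process and terminal proteins implicated in it (for example
    screen hits), finds a connected subnetwork linking every terminal to the
    anchor set while trading off total subnetwork weight against per-terminal
    path lengths through a parameter alpha in [0, 0.5]. Enumerates
    margin-bounded ensembles of near-optimal solutions to derive per-node
    confidence scores, computes network-propagation proximity features to the
    anchor and terminal sets, and trains a random-forest layer that rescores
    candidate nodes, finalizing the result as a minimum spanning tree.
    Includes converters for KGML pathway XML, OBO detection-method
    ontologies and tab-separated edge lists, a merger for interaction
    databases with detection-method reconciliation, and a synthetic benchmark
    generator that plants ground-truth pathways in random background
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
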