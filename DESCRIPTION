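Package: neiblp
Title: Neighborhood-Enhanced Link Prediction in Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural similarity indices for predicting missing edges in
    undirected, unweighted bipartite networks such as drug-target interaction
    maps. Implements the NeiBLP index, which scores an unconnected cross-side
    pair by combining degree-normalized resource allocation over the
    length-three paths of its quadrangle graph (QDRA) with a same-type
    resource-allocation reinforcement term (QSRA), together with classical
    neighborhood, local-community, path-count, and projection baselines
    (CN, JC, AA, RA, LCL, CAR, CAA, CRA, L3, LP3, LP35, LPOP, NBI, BPR).
    Includes edge-list and Matrix Market input, deterministic score output,
    train/probe edge splitting, exact and sampled AUC plus precision-at-L
    evaluation over repeated random splits, synthetic network generators
    (heavy-tailed configuration model and planted blocks), small pinned toy
    networks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
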