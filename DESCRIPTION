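Package: superspreadr
Title: Predicting Top SIR Superspreaders in Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and predicts the most influential spreading nodes
    (superspreaders) in directed, unweighted networks under the
    susceptible-infectious-recovered (SIR) epidemic model. Provides edge-list
    readers for common repository dialects, seven node centrality indicators
    (out-degree, one- and two-hop neighbourhood degree sums, core number,
    closeness, PageRank, eigenvector), event-driven continuous-time SIR
    simulation with per-node influence estimation, epidemic-threshold
    estimation via the outbreak-size variability peak, single-centrality
    ranking evaluation (recognition rate, precision function, bootstrap
    confidence intervals), and multi-centrality superspreader classification
    with a polynomial-kernel support-vector machine tuned by cross-validation.
    Includes deterministic fixtures and seeded random-network generators
    (including a planted core-periphery benchmark with ground-truth influence)
    and command-line style drivers with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
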