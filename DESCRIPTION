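Package: mesocircuit
Title: Connectivity-Based Neuronal Classification and Mesoscale Circuit
    Analysis
Version: 0.1.0
Authors@R:
    person("Mesocircuit", "Developers", email = "mesocircuit@example.org",
           role = c("aut", "cre"))
Description: Infers mesoscale brain circuits from weighted potential
    connectomes. A weighted neuron-to-neuron strength matrix is converted
    to connection probabilities under a binomial overlap model, an
    ensemble of binary connectomes is sampled and each is clustered by
    adjacency spectral embedding followed by Gaussian-mixture modelling
    with BIC model selection. The per-graph clusterings are merged by
    modified iterative voting consensus into connectivity-based cell
    classes, from which a stochastic-block-model circuit is estimated.
    The circuit is analysed with random-walk absorption and driftiness
    measures, graph-theoretic hub detection, biomarker mappings
    (posterior tables, mutual information, adjusted Rand index) and
    developmental growth statistics. A synthetic stochastic-block-model
    connectome generator makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
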