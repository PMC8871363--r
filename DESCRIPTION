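Package: grnattention
Title: Discriminating Gene Regulatory Network Architectures with
    Dual-Attention Recurrent Forecasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates stochastic protein-expression time series from
    archetypal gene regulatory network (GRN) architectures with a Gillespie
    algorithm driven by Hill-type activation and repression propensities,
    forecasts the traces with a parallel dual-attention encoder-decoder
    recurrent neural network (one forecaster per target gene), and analyses
    the learned input-attention matrices as weighted graphs.  Per-node graph
    descriptors (Barrat weighted clustering coefficient, betweenness
    centrality, Kleinberg hub score) and the response of the forecast to
    Gaussian perturbation of the target gene are assembled into
    architecture-level feature matrices, which are compared by hierarchical
    clustering, silhouette-selected partitions, principal component analysis,
    an information-based generalized Robinson-Foulds tree distance and the
    variation of information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
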