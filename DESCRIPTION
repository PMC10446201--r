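Package: adaptrewire
Title: Adaptive and Spatial Rewiring of Directed Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the self-organization of directed, weighted, spatially
    embedded networks under adaptive (functional) rewiring driven by
    consensus and advection kernel dynamics, combined with spatial rewiring
    principles (wiring-distance minimization and alignment to a lateral or
    radial vector field). Provides the full measurement suite for the evolved
    networks: average efficiency, connected node pairs, convergent and
    divergent hubs, convergent-divergent units with source/target/intermediate
    decomposition, intermediate-subgraph density, and directed weighted
    modularity, together with a seeded multi-run experiment runner for
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
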