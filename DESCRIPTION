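Package: syntenyDecay
Title: Analytical and Simulation Models of Synteny Block Size Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form synteny block size distributions for four models of
    genome rearrangement between a pair of genomes: uniform single breakpoints
    (random breakage), correlated breakpoint pairs mimicking inversions
    (correlated breakage), their combination, and Markov-chain breakpoint
    hotspots (fragile breakage). Includes an event-driven stochastic simulator
    of genome breakage on a gene-adjacency graph, Kullback-Leibler divergence
    fitting of each model to empirical block size tables with bounded
    multi-start local optimization, and conversion of fitted parameters into
    breakpoint rates per million years, hotspot fractions and physical spot
    lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
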