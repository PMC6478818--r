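Package: moranfix
Title: Fixation Probability and Time for the Moran Process on Population Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and stochastic computation of fixation probability,
    absorption time, and conditional fixation time for the Moran
    birth-death process on arbitrary weighted population-structure
    graphs. Provides full-state absorbing-Markov-chain solvers,
    symmetry-reduced (lumped) solvers for complete, star, and weighted
    complete bipartite graphs scaling to populations of thousands,
    seeded Monte Carlo simulation, enumeration of all connected graphs
    of small size, uniform and temperature initialization schemes,
    Pareto-front tradeoff analytics, and the effective rate of
    evolution combining mutation rate, fixation probability, and
    fixation time.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
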