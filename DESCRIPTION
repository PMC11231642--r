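Package: navbank
Title: Navigation-Map Module Banks and Randomized Nearest-Neighbour Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the planning subsystem of a brain-inspired cognitive
    architecture in which a bank of duplicated navigation modules each builds
    a candidate tour over tagged locations by a randomized nearest-neighbour
    rule, and the shortest tour across the bank is executed. Provides
    navigation-map grids with instruction-driven goto() tagging, the
    small_plan() tour-construction primitive with position-weighted and
    value-weighted selection probabilities, an exact Held-Karp tour oracle,
    and a Monte Carlo experiment harness with Welch one-tailed t-tests for
    comparing bank sizes and weighting schemes on symmetric distance tables.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
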