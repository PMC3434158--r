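Package: dcindex
Title: Distributional Consistency for Spatiotemporal Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how consistently a population of unmarked animals
    occupies an array of sites over time, while controlling for changes in
    population size. The distributional consistency (DC) index compares
    observed site-use patterns against the combinatorial maximum achievable
    given the observed per-step population sizes, yielding a score between 0
    (every site used in at most one time step) and 1 (identical occupancy in
    every time step). Includes multi-scale utilities for aggregating sites
    (grain) and subsetting regions (extent), Monte Carlo studies of
    robustness to survey error for count and presence/absence data with a
    regression-based error correction, a dispersal simulation linking
    individual movement rates to DC, and reading/writing of survey matrices
    as delimited text with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
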