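Package: mycotrade
Title: Co-Evolution of Resource Trade Between Plants and Mycorrhizal Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation toolkit for the co-evolution of resource trading
    strategies between a plant and a mycorrhizal fungus. A pair of coupled
    recursive growth equations describes one plant-fungus pair gathering
    carbon and phosphorus, exchanging (or taking) fixed shares of their
    specialised resource, and growing by Liebig's law of the minimum over a
    ten-step lifecycle. On top of this fitness model the package computes
    coupled plant/fungus fitness landscapes over the strategy plane,
    classifies interaction types (mutualism, parasitism, competition) against
    the no-exchange baseline, runs an individual-based evolution model of the
    heritable trading strategy with mutation and fitness-proportional
    selection, detects and stability-tests stable resource exchange strategy
    areas, and sweeps the full grid of nutrient uptake efficiency
    combinations to characterise where stable mutualism, mixed
    mutualism-parasitism, or no stable strategy evolves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
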