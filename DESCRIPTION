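Package: herbgame
Title: Evolutionary Game Models of Plant Tolerance to Herbivory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Solves a two-player foraging game between a plant, whose
    strategy is season-total root and shoot production, and an optimally
    foraging herbivore attacking either tissue. Computes evolutionarily
    stable growth strategies under no damage, fixed damage fractions, or
    damage co-determined with growth at a Nash equilibrium; sweeps
    equilibria across nitrogen gradients; quantifies compensatory growth
    with log response ratios against the ln(1 - d) no-compensation floor;
    and analyses randomized complete block clipping experiments, with a
    matching synthetic-data generator for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    numDeriv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
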