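Package: coralhue
Title: Coral Hue Diversity, Reef Colour Dissimilarity, and Reef Fish Richness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies organism colouration from cropped photographs as
    discrete multidimensional colour histograms, classifies histogram bins
    into a 267-category ISCC-NBS-style colour system, and aggregates
    per-species hue profiles into ecoregion-level hue diversity. Fits the
    regression suite relating reef fish species richness (total, per fish
    family, and per oceanic region) to coral species richness and coral hue
    diversity, with AIC model selection; computes earth mover's distance
    colour dissimilarity between reef seascape images; and pools
    bleached-versus-healthy fish responses as Hedges' d standardized mean
    differences under a DerSimonian-Laird random-effects model. A synthetic
    data generator with recorded ground truth makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    png,
    jpeg,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
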