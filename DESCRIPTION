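Package: photorestrict
Title: Limitation, Contribution and Control Analysis of Leaf Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies photosynthetic restrictions from leaf gas-exchange
    response curves within a single finite-interval framework. Fits
    non-rectangular hyperbolas to CO2- and light-response curves, couples
    the biochemical demand curve to the stomatal and mesophyll CO2 supply
    chain, and partitions changes in assimilation into per-input marginal,
    total and relative contributions, limitations, sensitivities and
    elasticities over K-interval transitions between physiological states.
    Ships the named analyses of the approach (stomatal, diffusional,
    stomatal/non-stomatal, treatment contribution, control, and light
    analyses) plus embedded worked-example data and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
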