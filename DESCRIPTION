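Package: fcaccess
Title: Floating Catchment Area Methods for Spatial Accessibility of Healthcare
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies potential spatial accessibility of healthcare supply
    (for example general practitioners) with the modified Huff-model
    three-step floating catchment area (MH3SFCA) method: continuous per-pair
    Gaussian distance-decay weights, Huff interaction probabilities that keep
    total demand constant, supply-demand ratios and per-location
    accessibility indices. Includes the classic baselines (2SFCA, E2SFCA,
    3SFCA, M2SFCA), network-based travel-time catchments from directed road
    networks via thresholded shortest paths, seeded synthetic-region
    generators emulating hectare population grids and car networks with
    one-way streets, quantile classification, reporting and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
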