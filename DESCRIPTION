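Package: gapmeter
Title: Sampling Coverage, Bias and Gap Analysis for Species Occurrence Data
Version: 0.1.0
Authors@R:
    person("gapmeter", "developers", email = "gapmeter@example.org", role = c("aut", "cre"))
Description: Quantifies inventory completeness, spatial aggregation and
    environmental coverage of species-occurrence datasets on an equal-area
    grid. Implements record cleaning (duplicate, coordinate-precision,
    extent, centroid and taxonomy filters), sample-based species
    accumulation curves with Clench asymptote estimation, per-cell landscape
    metrics from binary habitat rasters, varimax-rotated principal component
    environmental spaces, Schoener's D overlap with a resampling null,
    average-nearest-neighbour point-pattern analysis, rarity scores and
    rank-based bias tests. Ships a synthetic-landscape and biased-survey
    generator with known ground truth so the whole pipeline is testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    mgcv,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
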