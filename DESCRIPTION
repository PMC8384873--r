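Package: paleocorridor
Title: Palaeoclimate Downscaling and Climatic Corridors Out of Africa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct climatic windows for human dispersal out of
    Africa from coarse palaeoclimate simulations. Implements dynamic and
    classical delta-method downscaling with shape-preserving (PCHIP-type)
    regridding, decadal-scale variability injection from annual simulation
    series, the Koeppen aridity index, sea-level-dependent land masks,
    corridor connectivity analysis on a quasi-uniform hexagonal grid with a
    bisection search for the critical precipitation (or aridity) tolerance,
    minimax sea-crossing width across a bathymetric strait, and a
    hunter-gatherer climate-tolerance threshold estimator. A synthetic-world
    generator with planted, analytically known ground truth makes the whole
    pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
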