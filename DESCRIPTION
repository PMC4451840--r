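Package: fallout
Title: Flight Tracks, Light-Pollution Exposure and Grounding Risk of
    Fledgling Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study "fallout", the mass grounding of burrow-nesting
    petrel fledglings attracted to artificial lights on their maiden flight
    to the sea. Computes per-flight movement metrics (duration, path length,
    tortuosity, speed, timing relative to apparent sunset) from GPS tracks;
    extracts nocturnal-radiance and terrain covariates from rasters for
    points, flight polylines and colony buffers; clusters nest burrows into
    colonies; runs exhaustive and Monte-Carlo randomisation tests,
    Monte-Carlo Spearman tests and Yates-corrected chi-square tests; ranks
    univariate grouped-binomial grounding-rate models by AICc; and
    back-calculates breeding population size from rescue counts. A synthetic
    island nightscape generator (terrain, coastal lights, colonies, biased
    correlated random-walk flights with phototaxis) provides a fully
    reproducible testbed mirroring the statistical structure of published
    rescue-campaign data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
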