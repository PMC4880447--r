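Package: wormgait
Title: Eigenworm Posture Decomposition and Locomotion Analysis for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of Caenorhabditis elegans crawling
    behavior. Converts binary worm images to 26-point midline skeletons and
    24 inter-segment angle time series, fits an eigenworm basis by principal
    component analysis, and decomposes posture into an undulation mode
    (eigenworms 1-2, the traveling wave) and a turning mode (eigenworms
    3-24) whose sum reconstructs the posture exactly. Provides centroid
    track metrics (speed, track curvature, displacement), behavioral-state
    detection (reversals, omega turns, pauses), oxygen-gradient navigation
    statistics (bearing, curving bias, bearing-binned event rates,
    population distribution profiles and chemotaxis indices), ratiometric
    calcium-trace processing coupled to behavior, trial-level aggregation
    utilities, and a synthetic-data generator with stored ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    pracma,
    zoo,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
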