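Package: threatscape
Title: Ensemble Species Distribution Models and Cumulative Threat Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing threats to timber species in data-poor
    tropical regions. Provides an ensemble species-distribution-modelling
    engine (pseudo-absence sampling, replicate 70/30 evaluation with AUC and
    the true skill statistic, permutation variable importance, AUC-gated mean
    consensus, 10th-percentile binarisation), an eight-factor anthropogenic
    and climatic threat index on a common 5-km grid with scenario-based
    sensitivity analysis, and overlay summaries of species exposure to threat
    classes and protected-area coverage. Includes a synthetic-data generator
    with known niche and threat structure so the full pipeline is testable
    without external downloads. Lightweight matrix-backed raster and polygon
    containers with ESRI ASCII grid and GeoJSON input/output are built in.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    ranger,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
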