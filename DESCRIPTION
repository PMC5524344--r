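Package: estuaryRF
Title: Barrier-Aware Random Forest Mapping of Sediment Contamination
    Hotspots in Estuaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-support pipeline for predicting the spatial
    distribution of sediment-bound contaminants in estuaries from sparse,
    spatially biased point samples. Parameterizes point-source exposure with
    least-cost ("as the fish swims") distances on a rasterized water domain
    that treats land as an impenetrable barrier, fits an out-of-bag validated
    random-forest regression of log contaminant concentration on sediment
    covariates and source-distance summaries, selects a parsimonious
    predictor set by a three-step (threshold, interpretation, prediction)
    procedure driven by permutation importance and nested out-of-bag errors,
    and discretizes predictions into low/medium/high contamination classes
    under tercile, quartile and octile-tail quantile schemes. Includes a
    synthetic-estuary generator so that every stage of the pipeline can be
    exercised and validated without external spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    mgcv,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
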