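Package: gutdyn
Title: Biotic Interaction Inference and Enterotyping for Longitudinal
    Gut Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological analysis of dense longitudinal 16S
    community profiles of the gastrointestinal microbiota. Implements
    first-difference log-abundance pairwise regressions to infer directed
    biotic interactions between genera, ecological classification of
    interaction pairs (cooperation, competition, commensalism, amensalism,
    exploitation), connectedness and keystone/foundation taxon diagnostics,
    limiting-similarity tests of within- versus between-phylum competition,
    subsampling robustness and co-occurrence comparisons, and temporal
    enterotyping with square-root Jensen-Shannon distances, partitioning
    around medoids and a Wald-Wolfowitz runs test. A synthetic community
    simulator with known interaction structure supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    vegan
Suggests:
    biomformat,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
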