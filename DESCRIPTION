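Package: esbundles
Title: Multi-Scenario Land-Use Simulation, Dynamic Ecosystem Service
    Valuation and Ecosystem Service Bundle Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for landscape-scale ecosystem service
    analysis under land-use change scenarios. Provides Markov-chain demand
    projection with scenario edits of the transition matrix, a cellular-automata
    patch allocator with neighbourhood weights and a decreasing conversion
    threshold, equivalent-factor ecosystem service valuation with NDVI dynamic
    correction and land-conversion contribution accounting, Pearson trade-off/
    synergy classification, K-means ecosystem service bundles with elbow
    selection of the cluster count, four-date bundle trajectory coding with
    stability typing, and geographical-detector driver attribution (q statistic,
    two-factor interactions, VIF screening). A synthetic-landscape generator
    with known ground truth makes every stage testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
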