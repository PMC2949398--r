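Package: ccanet
Title: Networks of Co-Occurring and Anti-Co-Occurring Cancer Gene Mutations
Version: 0.1.0
Authors@R:
    person("CCA", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses networks of cancer genes whose somatic
    mutations co-occur or are mutually exclusive across tumour samples.
    Provides pairwise Fisher exact tests on per-pair contingency tables
    restricted to co-sequenced samples, network construction at a p-value
    cutoff with Benjamini-Hochberg false discovery rates, topology metrics
    (degree, clustering coefficient, components, shortest-path distances),
    randomization tests against edge-rewiring and link-resampling null
    models, pathway co-membership and signal-type usage analyses,
    expression-similarity-versus-distance analysis, mutation-frequency
    contrasts, module-level enrichment, and a synthetic-data generator
    with planted co-occurring and exclusive pairs so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
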