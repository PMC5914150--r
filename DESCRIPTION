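Package: netselect
Title: Genetic-Algorithm Feature Selection of Brain Network Metrics for
    Classifying Cognitive States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for two-state classification of
    functional brain networks.  Builds Fisher-z functional connectivity
    matrices from ROI time series, reduces them to positive-edge binary
    graphs, computes nodal graph metrics (degree, clustering coefficient,
    betweenness centrality) and Newman modularity, and selects the subset
    of regional metrics that maximizes leave-one-subject-out
    cross-validated RBF support-vector-machine accuracy using a
    Holland-style genetic algorithm, with a significance-based paired
    t-test baseline for comparison.  Includes a synthetic two-condition
    cohort generator with planted discriminative network structure for
    validation without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
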