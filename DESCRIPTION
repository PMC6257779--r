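Package: lagnet
Title: Lag-1 Dynamic Bayesian Network Inference and Time-Point Robustness
    for Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs directed gene regulatory networks from short
    expression time series by first-order conditional-dependence scoring
    with multiple-regression pruning (a lag-1 dynamic Bayesian network
    estimator), and quantifies how individual time-point measurements
    affect the reconstruction. Provides a VAR(1) simulator with known
    ground-truth structure, a panel of network statistics (average degree,
    diameter, average path length, betweenness, clustering coefficient,
    centralization, global efficiency, maximum vulnerability), power-law
    degree-distribution fits, a systematic time-point-deletion experiment
    with a relative diversity score, confusion-based network comparison
    (sensitivity, precision, F-measure), and cross-network edge-overlap
    analysis.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
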