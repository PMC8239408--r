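Package: npanet
Title: Network Perturbation Amplitude Scoring of Causal Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse causal reasoning on literature-curated causal
    networks written in the Biological Expression Language (BEL 1.0 subset).
    Parses BEL statements, compiles them into a signed directed functional
    layer, attaches signed gene signatures (a transcript layer) to inferable
    nodes, and scores differential gene expression profiles with a Network
    Perturbation Amplitude (NPA) statistic: signed-mean node activities, a
    quadratic consistency fit of node coefficients over the network, parametric
    Monte Carlo confidence intervals, and 'o'/'k' permutation companion
    statistics. Includes leading-node decomposition, hub and bottleneck
    topology diagnostics, Cytoscape-compatible import/export (SIF, GraphML),
    and a synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
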