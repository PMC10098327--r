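Package: stxmicro
Title: Single-Cell State-Transition Analysis of Microglia Across Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis chain for detecting condition-driven
    cell-state transitions in multi-condition single-cell RNA-seq, built
    around a dual partial-least-squares (PLS) real-virtual cell-pair
    projection: quality control, log-normalization, highly-variable-gene
    selection, PCA embedding, shared-nearest-neighbor graph clustering and
    marker-panel annotation; adaptive coefficient-of-variation gene
    filtering and dual-PLS state-transition profiles with hypergeometric
    cluster-to-condition assignment; intersection of bulk RNA-seq and
    proteomic differential tables; protein-protein interaction network
    centralities with median-of-centralities hub scoring and MCODE-style
    dense-subgraph detection; and local hypergeometric over-representation
    analysis against GMT gene-set collections. A negative-binomial
    synthetic-data generator with planted condition effects makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
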