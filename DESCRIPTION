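Package: acnet
Title: Activity Cliff Networks and Their Reduction to Matching Molecular
    Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds activity cliff (AC) networks from compound-potency data
    and reduces them to interpretable networks of matching molecular series
    (MMS). Compounds are decomposed by systematic single-cut matched
    molecular pair (MMP) fragmentation under size restrictions; MMP-cliffs
    (analog pairs with at least a 100-fold potency difference) become the
    edges of a compound-level network, while analog series sharing a common
    core become the nodes of a reduced network whose edges are
    structurally analogous series related by core-MMPs. Includes
    ChEMBL-style activity-record curation, R-group table export for series
    and series pairs, Cytoscape-ready network export (GraphML and SIF), and
    a synthetic analog-series generator with exact ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    cli,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
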