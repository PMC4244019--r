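Package: telofold
Title: Cross-Cell-Type Fold-Consistency Screening for Telocyte-Specific Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cell-type-specific up- and down-regulated genes from
    multi-study expression profiles by a fold-consistency rule: per-gene relative
    ratios of every comparator cell type against a reference cell type (here,
    pulmonary telocytes at culture days 5 and 10), an all-comparisons consistency
    classification, and threshold binning of the minimum fold at >0, >1 and >4.
    Includes probe-level I/O with annotation filtering and probe-to-gene
    aggregation, cross-study harmonization (normalization, replicate averaging,
    symbol-intersection merging, chromosome restriction), publication-style summary
    tables, top-N gene ranking, hierarchical clustering of cell-type profiles,
    interaction-network overlays on selected gene sets, a multi-study synthetic
    expression simulator with planted marker genes, and recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
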