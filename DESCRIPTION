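Package: xconcord
Title: Cross-Species Concordance and Network Analysis of Disease Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cross-species comparative transcriptomics of
    neurodegenerative disease models. Implements direction-aware filtering of
    differential-expression summary tables, graph-based tri-species homology
    concordance calling over merged pairwise ortholog maps, resampling null
    distributions for cross-species overlap statistics, confidence-thresholded
    protein-protein interaction network construction with map-equation
    community detection and randomized-background connectivity nulls,
    hypergeometric cluster comparison and Fisher gene-set enrichment,
    centrality-based candidate prioritization, and scoring of longitudinal
    behavioral (negative geotaxis) screens. A synthetic-data generator
    reproduces the statistical structure of the full pipeline so that every
    stage can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
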