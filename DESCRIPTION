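Package: gangliostat
Title: Spatial Organization and Co-Expression Module Architecture of
    Sensory Ganglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistics for in-situ transcriptomics of sensory ganglia and
    for cross-dataset single-cell atlases. Implements volume-normalized
    cell-type distance matrices and neighbor scores, convex-hull
    tissue-edge zonation summaries, post-processing of weighted
    co-expression (WGCNA-style) module eigengenes (redundant kME-based
    gene assignment, relative magnitude, digitized cluster profiles,
    signal width and uniqueness, identity bar decomposition, bin-matched
    per-cell gene-set scores), module-by-regulon Fisher overlap
    enrichment with Benjamini-Hochberg adjustment, and consensus
    cell-type labeling across datasets with a probabilistic
    cross-similarity matrix. Ships a synthetic-data generator producing
    clustered, radially zonated tissue point patterns and expression
    matrices with planted module structure, so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    nnet,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
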