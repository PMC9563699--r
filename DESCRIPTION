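Package: coexweave
Title: Horizontal Integration of Transcriptomics Datasets via Weighted
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of one or more bulk transcriptomics datasets
    ("layers") through transformation-based horizontal integration. Each
    normalized expression matrix is filtered to its most variant genes,
    converted to a weighted gene co-expression network by thresholding
    pairwise correlations (cutoff selection guided by scale-free topology
    statistics), and the per-layer networks are integrated by union or
    intersection with configurable multi-edge weight resolution. The
    integrated network is partitioned into co-expression modules by
    community detection, modules are summarized by their mean Group
    Fold-Change per condition, and interpreted through hypergeometric
    over-representation analysis against GMT gene-set collections,
    including transcription-factor target libraries. A synthetic multi-layer
    fixture generator with planted modules and group effects supports
    end-to-end testing, and a config-driven pipeline records every
    parameter for reproducible reruns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
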