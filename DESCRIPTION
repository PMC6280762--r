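Package: clonescan
Title: Discovery of Low-Frequency Clonal Mosaic Variants in Multi-Biopsy Deep Amplicon Sequencing
Version: 0.1.0
Authors@R: person("clonescan", "developers", role = c("aut", "cre"),
    email = "maintainers@clonescan.invalid")
Description: Tools to detect low-frequency ("selfish") clonal mosaic mutations
    in ultradeep amplicon sequencing of spatially structured tissue biopsies,
    such as radially dissected testis slices.  Implements per-position
    background error modelling with batch-covariate normalization, robust
    outlier variant calling, a tiered prioritization cascade, spatial
    clonal-event analysis on a biopsy adjacency graph, and pathway-enrichment
    statistics.  Includes a fully seeded synthetic-data generator emulating
    panel, biopsy layout, clone placement and overdispersed pileup counts, so
    the entire pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    matrixStats,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
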