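Package: nichestat
Title: Spatial, Imaging and Screen Statistics for Tumor Microenvironment Niches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Neighborhood statistics for tumor microenvironment studies that
    combine spatial transcriptomics, multiplexed ion beam imaging, pooled
    CRISPR screens and bulk tumor cohorts. Implements spot-lattice neighbor
    graphs and sliding-window spatial gene correlation, cluster-adjacency and
    ligand-receptor permutation tests, cell co-localization and
    tumor-infiltration compartment statistics, screen log2 fold-change
    processing with arm-comparison permutation FDR, co-essentiality network
    construction, binned-background gene module scoring, and copy-number-loss
    effect analysis. Ships synthetic-data generators with ground-truth labels
    so every statistic can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
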