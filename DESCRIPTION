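Package: connectogene
Title: Connectome Network Statistics and Imaging Transcriptomics with
    Spatially Constrained Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links disease-burden biomarkers to brain functional
    connectivity and regional gene expression. Provides the
    network-based statistic (edge-wise general linear models,
    suprathreshold components, family-wise-error permutation p-values
    with Freedman-Lane covariate handling), per-region association maps
    (partial Spearman correlations and group-by-biomarker interaction
    models with false-discovery-rate control), partial least squares
    regression of a region-by-gene expression matrix onto regional
    maps with sphere-rotation ("spin") spatial permutation nulls and
    bootstrap gene ranking, and three enrichment procedures
    (hypergeometric over-representation, expression-weighted cell-type
    bootstrap, candidate gene-list permutation). A seeded synthetic
    data module generates atlases, cohorts, connectomes, expression
    matrices and cell-type references with the statistical structure
    the analyses assume, so the whole pipeline runs and is validated
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
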