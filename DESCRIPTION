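Package: crisprSelect
Title: Selective-Essentiality Analysis of Pooled CRISPR Knockout Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores two-arm (vehicle versus drug) pooled CRISPR knockout
    screens for selective gene essentiality. Implements sgRNA- and gene-level
    log2 fold-change scoring with pseudocount normalization, reference-based
    scaling anchored on non-targeting controls (0) and core-essential genes
    (-1), and z-scored differential dependency for synthetic-lethality hit
    calling. Includes a generative screen simulator with planted fitness
    effects for benchmarking and parameter-recovery testing, plus small
    assay statistics used alongside such screens: composite RNA in situ
    hybridization scores, autophagic-flux reporter indices, Bliss synergy
    excess, and phosphoinositide HPLC peak percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
biocViews: CRISPR, PooledScreens, FunctionalGenomics, GeneTarget, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
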