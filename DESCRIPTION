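Package: gbmimmune
Title: Immune Microenvironment Profiling of Glioblastoma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterise the immune microenvironment of
    glioblastoma (GBM) from bulk and single-cell transcriptomes. Bulk
    tumours are scored against an immune cell-type signature compendium
    and assigned to consensus immune clusters (CICs) by nearest-centroid
    classification on Spearman rank correlation. Single cells are
    classified into tumour and immune compartments by marker positivity
    rules, with per-cell immunosuppressive-gene burden and receptor-ligand
    co-expression statistics. Two-group cohort comparisons (cluster vs
    cluster, or median-split high/low expressors of a surrogate gene) use
    the Mann-Whitney test. A synthetic-data module generates bulk cohorts
    and single-cell mixtures with known ground truth so every stage of the
    pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    jsonlite,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
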