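Package: coremod
Title: Cross-Tissue Core Expression Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers compact gene-expression modules that discriminate
    treated from control samples consistently across tissues. The pipeline
    deconvolves per-timepoint (age/recovery) effects from the treatment
    effect with a per-gene linear model, infers candidate pathway-activity
    modules in one inference tissue by greedy condition-responsive-gene
    (CORG) aggregation, validates them in other tissues by consensus
    feature elimination over ensembles of regularized linear discriminant
    classifiers, retains modules surviving in at least half of the
    validation tissues as core modules, and projects the core modules onto
    a protein-protein interaction network. Also provides moderated
    t-statistics, iterative group analysis (iGA) enrichment of GO terms and
    sub-pathways with permutation nulls and Benjamini-Hochberg FDR,
    pairwise hypergeometric overlap tests between tissues, microarray-style
    preprocessing (missing-probe filtering, KNN imputation, quantile
    normalization, sibling-probe aggregation), and a fully seeded synthetic
    study generator with planted modules for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
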