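Package: demix
Title: Reference-Free Cell-Type Deconvolution and Interpretation of Bulk Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised (reference-free) cell-type deconvolution of bulk
    gene-expression and DNA-methylation (beta-value) matrices. Factorizes a
    features-by-samples matrix X into cell-type profiles T and simplex-constrained
    proportions A with several engines: alternating constrained least squares
    NMF, an EDec-style box-constrained factorization for beta-values, FastICA
    with marker-based component scoring, and a simplified convex-geometry
    (CAM-style) vertex search. Includes RPM and median-of-ratios normalization,
    log2/pseudo-log transforms, coefficient-of-variation feature selection,
    PCA-eigenvalue scree guidance with an automatic elbow suggestion for the
    number of components, biological interpretation of components by preranked
    GSEA or hypergeometric over-representation analysis against GMT gene-set
    collections (with CpG-to-gene aggregation for methylation), and a seeded
    synthetic-mixture simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    quadprog,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DeconvolutionResult-methods.R'
    'OmicsMatrix-methods.R'
    'constrained-ls.R'
    'demix-package.R'
    'engine-cam.R'
    'engine-ica.R'
    'engine-nmf.R'
    'genesets.R'
    'interpret.R'
    'pipeline.R'
    'preprocess.R'
    'scree.R'
    'simulate.R'
    'utils.R'
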