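Package: immunofusion
Title: Multi-Source Data Fusion for Dissecting Tumor Immune-Evasion Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative framework for studying how tumors regulate
    immune-evasion genes. Tumor cohorts are subtyped by consensus
    non-negative matrix factorization over immune-gene expression, each
    subtype is contrasted against a normal cohort with two negative-binomial
    differential-expression tests combined by a consensus rule, natural-killer
    ligand genes are categorised by role and direction, copy-number/expression
    Spearman correlation separates CNV-explained genes from candidates for
    transcription-factor regulation, and an ATAC-seq based algorithm makes
    per-sample regulator-to-target calls from promoter-proximal peak
    accessibility, motif occurrence, and single-sample expression tests.
    Kaplan-Meier stratification by expression tertiles closes the loop. A
    synthetic-cohort generator with planted ground truth supports end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    survival,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Clustering,
    DifferentialExpression, CopyNumberVariation, Epigenetics, ATACSeq,
    Survival, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cnvcorr.R'
    'diffexpr.R'
    'immunofusion-package.R'
    'io.R'
    'motifs.R'
    'nmf.R'
    'pipeline.R'
    'regulatory.R'
    'simulate.R'
    'survival.R'
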