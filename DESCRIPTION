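Package: promethyl
Title: Promoter Methylation-Expression Integration in CIMP-Stratified Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A promoter-centric framework for identifying genes whose expression is
    explained by promoter DNA methylation in tumor cohorts stratified by CpG island
    methylator phenotype (CIMP). Provides probe filtering and promoter mapping for
    Illumina 450K-style methylation data, TMM normalization of RNA-seq counts,
    CIMP-index stratification, integrated differential methylation/expression
    analysis with a five-way classification, six Spearman- and regression-based
    methylation-expression association scorers with gene selection and cross-method
    comparison, an external-consistency epigenetic silencing metric, and a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
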