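Package: pdlsig
Title: PD1-Ligand Reverse-Signalling Transcriptomics for Fibroblast-Like
    Synoviocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Donor-blocked differential expression analysis of a five-condition
    soluble-PD1 stimulation design in fibroblast-like synoviocytes, with
    empirical Bayes moderated t-tests under a block-exchangeable intra-donor
    correlation structure, TMM normalization and precision weights, bootstrap
    stability scoring of fold-change rankings, delta-log2FC dampening
    quantification, compound sPD1-responsive gene calling with PD-L1/PD-L2
    knockout attribution, comparative-Ct qPCR validation, and cohort-level
    single-cell QC, pseudobulk and single-sample gene-set enrichment
    utilities. Ships negative-binomial bulk, qPCR and single-cell simulators
    with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cohort.R'
    'diagnostics.R'
    'io.R'
    'model.R'
    'normalize.R'
    'pdlsig-package.R'
    'pipeline.R'
    'qpcr.R'
    'responsive.R'
    'simulate.R'
    'utils.R'
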