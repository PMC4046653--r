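Package: polysomeTE
Title: Translational Efficiency and Translational Regulation from Polysome-Pool
    Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of translational profiling experiments in which
    sucrose-gradient fractions are combined into non-translated, intermediate
    and ribosome-bound mRNA pools and profiled on expression arrays. Computes
    per-gene relative expression across pools and translational efficiency
    (the ribosome-bound fraction), tests for treatment-induced translational
    regulation with an empirical-Bayes moderated one-sample t-test and
    Benjamini-Hochberg FDR control, and performs hypergeometric gene-set
    over-representation among poorly translated genes. Includes a synthetic
    data generator emulating a paired 3-pool, 2-treatment, 3-replicate design
    with known ground truth, so every stage of the pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
biocViews: GeneExpression, Transcriptomics, DifferentialExpression,
    Microarray, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
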