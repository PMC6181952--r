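Package: CohortScreen
Title: Multi-Cohort Consistency Screening and Prognostic Signature
    Evaluation for Cancer Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening candidate genes across multiple tumor
    expression cohorts by anchor-gene Spearman correlation and
    tumor-versus-normal alteration consistency, empirical-Bayes moderated-t
    differential expression of two-group perturbation experiments,
    hypergeometric over-representation analysis, and quartile-based
    Kaplan-Meier evaluation of single-gene and mean-signal composite
    prognostic signatures. Includes array-style normalization (background
    correction, log2 transform, quantile normalization, detection-p
    filtering), qPCR and ChIP-qPCR relative-quantification statistics, and
    a seeded synthetic multi-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
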