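Package: mclnet
Title: Network-Based Transcriptomics and Drug-Combination Screening for
    Staged Mantle Cell Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A modular pipeline from staged gene expression to candidate
    therapeutics for mantle cell lymphoma and related B-cell malignancies:
    quantile normalization and sample-structure diagnostics with SVM-based
    regrouping, empirical-Bayes moderated-t differential expression,
    mutual-information co-expression networks (Kraskov k-nearest-neighbour
    estimator with MRNETB inference and quantile hard-thresholding),
    cross-condition module alignment by joint spectral clustering with
    eigengap model selection, hypergeometric over-representation analysis
    with fold enrichment, action-aware drug repurposing from drug-target
    catalogs, and network-proximity screening of drug combinations
    (separation, degree-preserving z-scores, complementary exposure).
    Includes generators for synthetic expression, interactome and drug
    catalog data with planted ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
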