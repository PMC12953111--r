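Package: lnmsig
Title: Projecting Bulk Lymph-Node-Metastasis Status onto Single Cells and
    Deriving a Regulon-Based Clinical Signature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for linking pathological lymph node
    metastasis (LNM) in a bulk transcriptomic cohort to cell states in
    single-cell RNA-seq data. Bulk two-group differential expression with
    empirical-Bayes moderated t-statistics defines directional gene sets;
    rank-based per-cell U-scores project the bulk phenotype onto single
    cells; composition shifts, penalized-cosine marker scores, regulon
    activity (area under the recovery curve) and regulon specificity
    (Jensen-Shannon) identify the metastasis-associated myeloid
    subpopulation and its governing transcription factor; the regulon's
    target genes are converted into a single-sample enrichment score with
    survival, tumor-mutational-burden, immunotherapy-response and
    drug-sensitivity readouts. A synthetic-data generator with a planted
    transcriptional program, planted regulon and score-linked outcomes
    makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    stats,
    survival,
    tools,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
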