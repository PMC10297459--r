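Package: ClockRegulome
Title: CLOCK Regulome Inference in Hepatic Stellate Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers a CLOCK transcription-factor regulome in hepatic stellate
    cells (HSCs) by integrating differential ATAC-seq chromatin accessibility
    between quiescent and activated HSCs, E-box (CACGTG) motif occurrence in
    peak sequences, and CLOCK-mutant versus wild-type expression fold-changes.
    Supporting analyses cover pairwise expression contrasts with
    Benjamini-Hochberg correction, direction-pattern clustering, primed-gene
    selection, hypergeometric gene-set over-representation, circadian period
    estimation from bioluminescence reporter traces (moving-average detrending
    and damped-cosine fitting), and liver-fibrosis cohort stratification by
    liver stiffness or FIB-4 score with Kruskal-Wallis and Dunn post-hoc
    comparisons. A synthetic-data module generates every input with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
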