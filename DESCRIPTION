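Package: pcllike
Title: Transcriptomic Classification of Plasma Cell Leukemia-Like Multiple Myeloma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs, calibrates, applies and evaluates a transcriptomic
    classifier that identifies newly diagnosed multiple myeloma (NDMM) tumors
    whose bone-marrow transcriptome resembles primary plasma cell leukemia
    (pPCL). Genes are ranked by their association with circulating tumor cell
    (CTC) levels on a log-odds scale, adjusted for tumor burden, with
    Benjamini-Hochberg false discovery rate control; the number of classifier
    genes is chosen by leave-one-out cross-validation; the decision threshold
    is the minimal score of pPCL tumors in the discovery set. Includes a
    synthetic-cohort generator with known ground truth, non-survival
    evaluation utilities (CTC prediction with sequential ANOVA variance
    decomposition, rank tests, Fisher's exact co-occurrence), and prognostic
    evaluation via Kaplan-Meier/log-rank, study-stratified Cox models and
    DerSimonian-Laird random-effects meta-analysis of hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr
Config/testthat/edition: 3
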