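Package: refstab
Title: Reference-Gene Stability Evaluation and Normalization for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting reference (housekeeping) genes for
    reverse-transcription quantitative PCR and for normalizing genes of
    interest against them. Implements four stability algorithms on
    quantification-cycle (Cq) data: the pairwise delta-Ct mean-SD method,
    a model-based intra/inter-group variance decomposition (NormFinder
    style), the geNorm M value with iterative exclusion, normalization
    factors and the V(n/n+1) gene-count rule, and GrayNorm scoring of all
    reference-gene combinations by condition-averaged 1/NF deviation.
    Rankings from several methods can be merged into a consensus by
    Cross-Entropy Monte-Carlo minimization of total Spearman footrule
    distance. Includes efficiency-corrected relative quantification with
    normalization-factor division and strategy comparison, plus a
    synthetic Cq-data generator with known ground truth for validating
    the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
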