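Package: cnaburden
Title: Arm-Level Copy-Number Burden Scoring and Expression Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aggregates gene-level GISTIC copy-number calls to chromosome-arm
    status with an inclusive two-thirds majority rule, counts per-case altered
    arms, classifies cases as CNA-high or CNA-low by a median split, scores
    immunohistochemistry intensity distributions on the 0-300 H-score scale
    with dichotomization at a multiple of the normal-tissue median, and runs
    the associated statistical layer (Fisher's exact test, Mann-Whitney U,
    Wilcoxon signed-rank, Welch t). Includes a seeded synthetic-cohort
    generator emulating TCGA-shaped lung tumor cohorts so the full analysis
    is reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
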