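Package: engraftr
Title: Donor Strain Engraftment Analysis for Multi-Donor FMT Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts faecal microbiota transplantation (FMT) donor-recipient
    pairings from strain-level metagenomic profiles. Computes per-species
    pairwise Jukes-Cantor (JC69) distances between dominant-strain consensus
    sequences, normalises them by the per-species median, calls donor strain
    matches at a distance threshold with baseline and placebo subtraction,
    sweeps thresholds against reference pairings to maximise F1, and
    quantifies donor recall and engraftment efficiency. Includes the
    downstream determinants-of-efficiency statistics (diversity metrics,
    PERMANOVA, linear mixed models) and a synthetic multi-donor cohort
    generator with ground-truth engraftment events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    stats,
    utils,
    vegan,
    lme4,
    lmerTest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
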