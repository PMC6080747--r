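Package: mucinif
Title: Nitrogenase Gene Screening in Metagenomes and 15N-Based Nitrogen
    Fixation Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two linked analyses of plant-associated nitrogen
    fixation. A phylogenetically anchored screen translates metagenomic
    reads in six frames, aligns them against curated nitrogenase (nif)
    reference peptide families with Karlin-Altschul E-value filtering,
    places candidate hits on per-gene trees, keeps only hits falling
    inside the reference clade, and normalizes the resulting counts by
    the single-copy marker recA. A companion set of estimators computes
    the percentage of plant nitrogen derived from the atmosphere (Ndfa)
    from 15N natural abundance or 15N enrichment field trials, plus the
    nitrogen-difference (Ndiff) estimate, with pooled t tests,
    single-degree-of-freedom contrasts, and Pearson correlations.
    Seed-deterministic simulators generate reference families, labelled
    metagenomes, and randomized-block field trials so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
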