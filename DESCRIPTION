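Package: somaticflow
Title: Downstream Somatic Variant Integration for Matched Tumor/Normal Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the downstream integration of
    matched tumor/normal whole-exome and transcriptome caller outputs:
    depth/allele-fraction/rarity variant filtering, somatic-versus-germline
    classification from matched-normal pileups, mutational burden per
    megabase of captured target, two-caller copy-number consensus with
    polymorphic-region filtering and focal-deletion queries, multi-caller
    fusion consensus with read-through triage, and multi-lesion clonal
    partitioning. Ships a seeded synthetic cohort generator that emulates
    caller output with known ground truth, so every stage can be scored
    against simulated labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr,
    stats,
    utils,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
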