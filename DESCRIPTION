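Package: chromoshatter
Title: Detection and Reconstruction of Radiation-Induced Chromoanagenesis
    from Binned Short-Read Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting chromoanagenesis
    (chromothripsis and chromoanasynthesis) in diploid F1 populations from
    short-read data summaries: standardized relative read coverage in
    genomic bins, copy-number segment calling with a level-shift rule,
    parental-allele-ratio confirmation of segment origin, novel DNA
    junction discovery from discordant read pairs with greedy contig
    assembly and base-exact breakpoint resolution, junction typing
    (microhomology / perfect / insertion) and orientation classing,
    breakpoint-graph reconstruction of the rearranged chromosome, and
    permutation-based tests of breakpoint enrichment in genomic features.
    Includes a seeded synthetic-data generator that emulates an irradiated
    F1 hybrid population with full rearrangement truth, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
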