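Package: ampsieve
Title: Mining Digestion-Survivable Antimicrobial Peptides from Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico pipeline for discovering antimicrobial peptides
    (AMPs) that survive gastrointestinal digestion. Protein sequences are
    scanned with a sliding-window antimicrobial propensity profile, digested
    in silico with pepsin under complete and partial digestion, and the
    released fragments are matched against the predicted antimicrobial
    stretches. Matched peptides are scored for resistance to intestinal
    proteases (cleavage stability score), combined with half-life derived
    decay rates, and ranked by a combined antimicrobial score. Includes a
    synthetic proteome generator with planted antimicrobial stretches and
    controlled pepsin-cleavable flanks so that every stage of the pipeline
    can be validated against known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
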