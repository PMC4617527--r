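Package: poolmut
Title: Mutation Calling and Clonality Correction for Pooled Reporter-Gene
    Plaque Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep amplicon sequencing of pooled mutant
    plaques from transgenic rodent mutation reporter assays (Muta(TM)Mouse
    lacZ). Parses per-position read-count pileups for barcoded pools run in
    technical duplicate, estimates per-position per-event background error as
    the cross-library median proportion, subtracts it, calls rare mutations
    against plaque-count-derived thresholds with replicate concordance,
    corrects recurrent mutation counts for clonal expansion with a
    limit-of-detection/linear calibration model, builds complement-collapsed
    mutation spectra, compares groups by Pearson chi-squared and Poisson
    regression, locates hotspots and homopolymer-associated indels, and runs
    mutants-per-sample power simulations. Includes a synthetic pooled-plaque
    data generator with known truth so every stage is testable without
    sequencing data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
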