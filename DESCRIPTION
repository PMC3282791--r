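Package: cnmosaic
Title: Allele-Specific Copy Number and Mosaicism Analysis for Paired SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cytogenetic analysis of paired tumor/normal SNP-array data.
    Computes paired copy number from log R ratios, partitions each genome into
    segments by recursive mean-difference splitting, detects splitting of the
    heterozygote B-allele-frequency band, classifies the underlying mechanism
    (mono-/bi-allelic amplification or deletion, copy-neutral LOH) by grid
    back-calculation of a two-population admixture model, estimates the
    aberrant-cell fraction (mosaicism), stacks per-sample events into recurrent
    cohort regions, tests region-phenotype associations with contingency
    tables, and matches affected genes against a drug-target table. Includes a
    synthetic cohort generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
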