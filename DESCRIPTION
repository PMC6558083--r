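Package: mosaicf
Title: Age-Partitioned Inbreeding from Homozygosity-by-Descent Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the level and age of inbreeding from SNP-array genotypes
    with a multi-class homozygosity-by-descent (HBD) hidden Markov model. The
    genome of each individual is modelled as a mosaic of HBD and non-HBD
    segments whose lengths are exponential with class-specific rates, so that
    each HBD class corresponds to a window of generations to the common
    ancestor. Provides forward-backward posteriors and per-class inbreeding
    coefficients (F_G), Viterbi and posterior-based calling of runs of
    homozygosity (ROH) with F_ROH and F_ROH>2Mb, and a correction that detects
    hemizygous copy-number deletions mistyped as ROH (via CNV-call intersection
    and log R ratio evidence) and subtracts them from all inbreeding metrics.
    Includes a synthetic-data generator emulating the assumed mosaic process,
    genotyping error, and intensity signatures of hemizygous deletions, plus
    PLINK PED/MAP text input, quality-control filters, and cohort reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    IRanges,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
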