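Package: chicpeaks
Title: Interaction-Peak Calling and Target-Gene Assignment for Capture Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls statistically significant chromatin interaction peaks from
    Capture Hi-C (CHi-C) di-tag counts at GWAS risk loci. Captured restriction
    fragments that failed are removed with a truncated negative-binomial filter
    on trans-ligation counts; background contact frequencies are modelled with
    negative-binomial regressions on fragment interactability and genomic
    distance within distance-percentile bins; upper-tail p-values are adjusted
    per locus with the Benjamini-Hochberg procedure. Includes replicate
    reproducibility checks, cross-cell-line peak comparisons (permutation
    sharing test, Jaccard clustering, non-parametric locus tests), putative
    target-gene assignment with nearest-gene comparison, and a synthetic-data
    generator with planted peaks for false-discovery and power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
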