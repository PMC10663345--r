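Package: endostat
Title: Absolute-Quantitation and Permutational Statistics for Endophytic
    Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for downstream analysis of
    amplicon sequence variant (ASV) tables from endophytic microbiome
    field surveys. Implements spike-in based absolute quantitation and
    admission filtering, read-count quality filtering, repeated
    rarefaction with Shannon, Pielou and Faith alpha diversity,
    compositional transforms (robust centred log-ratio, additive
    log-ratio against a spike reference), a grid of beta-diversity
    metrics (Bray-Curtis, Jaccard, weighted UniFrac, Euclidean),
    core-microbiome membership rules including indicator-species
    analysis, permutational multivariate ANOVA with sequential sums of
    squares and blocking, PERMDISP-style multivariate dispersion tests,
    and a within-individual tissue-homogeneity statistic. A
    Dirichlet-multinomial synthetic-data generator reproduces the
    design structure of a multi-genotype, multi-tissue, multi-stage
    field experiment so that every stage of the pipeline can be tested
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    jsonlite,
    phyloseq,
    picante,
    readr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
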