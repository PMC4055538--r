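Package: cogdepth
Title: Depth-Stratified Functional Profiling of Marine Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative functional profiling of depth-stratified marine
    metagenomes from counts of reads assigned to clusters of orthologous
    groups of proteins (COGs). Provides rarefaction subsampling to a common
    read depth, exact two-sample count tests with Benjamini-Hochberg false
    discovery rate control, per-water-column screens for depth-related COGs,
    derivation of photic and aphotic core marker sets by Welch's test, a
    log2 photic:aphotic abundance-ratio diagnostic with reference bands and
    zone classification, identification of COGs associated with oxygen
    minimum zones together with a dissolved-oxygen threshold estimate,
    phylum-level taxonomic summaries of marker COGs, bootstrap-supported
    hierarchical clustering of datasets, and a synthetic-data generator that
    plants known photic, aphotic and oxygen-responsive markers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
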