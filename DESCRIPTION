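Package: barcodegap
Title: ITS2 Barcode Evaluation: Trimming, Barcoding-Gap Analysis,
    Identification and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the classical ITS2 DNA-barcode
    evaluation pipeline for closely related plant species: profile-HMM
    excision of the conserved 5.8S and 28S flanks, progressive multiple
    alignment, Kimura 2-parameter distances with intra/interspecific
    partitioning and barcoding-gap assessment, Wilcoxon rank-sum comparison
    of the two distance sets, leave-one-out species identification by the
    nearest-distance and best-local-alignment (BLAST1-style) methods,
    neighbor-joining clustering with nonparametric bootstrap support and
    species-monophyly checks, haplotype collapse with intraspecific
    variable-site reporting, and a Kimura-model sequence simulator that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
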