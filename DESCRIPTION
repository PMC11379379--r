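Package: emsmap
Title: EMS Mutagenesis Probability Maps for Forward Genetic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds per-nucleotide mutation probability maps for ethyl
    methane sulfonate (EMS) mutagenesis from two signals that shape the
    mutation spectrum: the five-base sequence context around each site and
    smoothed DNA-binding-protein occupancy tracks. A baseline context table
    (P0 = mutated occurrences over genomic occurrences of each 5-mer) feeds
    a random-forest regressor together with chromatin features; the fitted
    per-strain, per-base probabilities are normalized for batch mutagen
    effectiveness and used to score pooled forward-genetic-screen sequencing:
    observed per-gene mutation counts are tested against their binomial
    expectation to call candidate causal genes. Includes evaluation tools
    (block validation, GC correlation, permutation feature importance) and a
    fully synthetic data generator (toy genomes, chromatin-like tracks,
    Bernoulli-mutagenized cohorts, phenotype-selected screen pools) so the
    whole pipeline runs without external downloads.
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
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    ranger,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
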