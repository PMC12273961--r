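Package: segmapr
Title: Mapping-by-Sequencing of Pooled Segregants for Forward Genetic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps causative mutations from forward genetic screens using
    bulked segregant analysis of pooled whole-genome sequencing data. From
    mutant and wild-type sibling pool VCFs (freebayes-style RO/AO allele
    observation counts), computes a windowed heterozygosity-difference SNP
    index, smooths it with a moving-average filter, and selects the
    zero-bounded homozygous candidate interval. Filters and annotates
    candidate point mutations inside the interval (segregation, mutagen
    likeness, gene-model consequence classes, optional SIFT scores), emits
    segregating insertion/deletion markers for recombinant mapping, and
    refines the interval from per-animal marker genotypes using
    recombination-frequency arithmetic. A synthetic incross simulator with
    known ground truth makes the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
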