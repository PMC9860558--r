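Package: popgenscan
Title: Population-Genomic Scans, Mixed-Model GWAS and Sweep Detection for
    Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy, end-to-end toolkit for population-genomic analysis of
    diversity panels of selfing crops such as sesame: site filtering of VCF
    genotypes, SNP functional annotation, windowed nucleotide diversity,
    Watterson's theta, Tajima's D and Weir-Cockerham FST, linkage
    disequilibrium decay with half-decay distance, joint FST / pi-ratio
    selective-sweep calling, multi-environment BLUP phenotypes, EMMAX-style
    mixed-model association scans, and favorable-allele effect tests.
    Includes a seeded synthetic-data generator (Balding-Nichols population
    structure, planted sweeps, founder-copying linkage, quantitative traits
    with known causal sites) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    jsonlite,
    lme4,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
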