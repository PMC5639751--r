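Package: rddmscan
Title: Transposable-Element Proximity and RdDM Effects on the Maize Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative transcriptome and epigenome
    analysis of RNA-directed DNA methylation (RdDM) mutants against wild
    type: genome transcribed-fraction estimation from alignment footprints
    with seeded down-sampling, two-sample comparison of expression
    distributions (Kolmogorov-Smirnov with a D-crit conjunction rule,
    Fisher zero-expression test, log2 expression binning, Mann-Whitney rank
    tests), strand-aware classification of genes by transposable-element
    context, 100-kb window co-localization of differentially expressed
    genes with a random-gene-set null, gene-identity permutation tests over
    nearest-TE distance and flanking DNA methylation, subgenome and
    homeolog-pair analysis, and 24-nt siRNA locus occupancy profiles. A
    synthetic-data module generates complete toy datasets with known
    injected effects so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
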