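Package: htrscan
Title: Detection and Population-Genomic Analysis of Horizontally
    Transferred Regions in Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrated detection of recent horizontally transferred
    regions (HTRs) between distantly related fungal genomes, from pairwise
    local-alignment matches (PAF or a built-in anchor matcher), with
    transposable-element masking, presence/identity scanning of HTR
    consensus sequences across genome panels, within-species diversity,
    linkage-disequilibrium and mating-type statistics from haploid variant
    calls, and gene-level selection inference combining McDonald-Kreitman
    count tables with a hierarchical Bayesian Poisson log-linear
    classifier. Includes a seeded synthetic-genome generator producing
    panels with planted HTRs, variants and selection effects of known
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    vcfR,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
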