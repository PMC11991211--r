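Package: IntroKASP
Title: Alien Introgression Breakpoint Mapping and KASP Marker Design for
    Wheat Translocation Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterises alien chromosome-segment introgressions in
    polyploid wheat from whole-genome resequencing and bulked-segregant
    data. Windowed read depth over a merged recipient+donor reference is
    segmented into present/absent runs to locate translocation
    breakpoints and size the added and deleted fragments; an F2
    bulked-segregant Delta-SNP-index scan with a simulation-based null
    envelope maps the trait-associated interval; and a six-criterion SNP
    filter cascade (missing rate, minor allele frequency, local SNP
    spacing, polymorphism information content, flanking GC content, even
    genomic distribution) selects sites and builds kompetitive
    allele-specific PCR (KASP) primer sets with FAM/HEX tails. A
    synthetic-data module simulates depth profiles, segregating F2
    populations with phenotype bulks, and gene annotations with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
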