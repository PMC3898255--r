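Package: degmorph
Title: Motif Analysis and Read Positioning for Plant RNA Degradome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dissects bulk plant degradome (PARE, degradome-seq, GMUCT)
    libraries beyond microRNA targets. Calls predominant uncapped 5'-ends
    per genomic region with a local dominance criterion and a binomial
    test, discovers short position-fixed sequence motifs anchored at those
    ends, profiles uncapped-read positioning around any motif or feature
    5'-end genome-wide via motif-oriented read positioning heat maps
    (MORPH) with Ward clustering, screens adaptor-mispriming artifacts,
    runs terminal base-composition QC, and ships a seeded synthetic-data
    generator with ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
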