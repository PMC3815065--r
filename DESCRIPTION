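Package: hapsweep
Title: Haplotype Classification, Network Inference, and Molecular-Clock
    Dating of Selective Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of a selected haplotype in a
    recombining autosomal region: linkage-disequilibrium block partitioning
    from recombination-rate maps, classification of phased chromosomes
    against named haplotype definitions, rooted nearest-neighbour mutation
    networks with recurrent-transition (recombination) flagging, single
    crossover reconstruction of recombinant haplotypes, and molecular-clock
    dating of a haplotype's most recent common ancestor with
    resampling-based effective sample sizes, exact Poisson confidence
    limits, and detection-power undercount correction.  Includes readers
    for phased VCF, IMPUTE-style hap/legend/sample panels and plain TSV
    matrices, plus synthetic-panel generators (star genealogies,
    infinite-sites mutation trees, single-crossover recombinants) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
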