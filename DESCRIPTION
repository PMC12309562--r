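Package: spritetel
Title: Telomere Contact Mapping from SPRITE Split-Pool Barcoding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts telomere-repeat reads from SPRITE (split-pool
    recognition of interactions by tag extension) sequencing data, assigns
    them to an artificial single-bin locus ("chrT"), builds 2/N-downweighted
    contact matrices, and analyzes the resulting genome-wide telomere
    contact track: distance-to-telomere decay, distance normalization,
    annotation enrichment tests, H3K9me3 peak proximity profiles, and A/B
    compartment eigenvector correlation. Also calls structural variants
    containing ectopic telomere repeats from soft-clipped long-read
    alignments, scores telomere-centromere adjacency in segmented FISH
    nucleus images with a randomization percentile test, and ships a seeded
    synthetic-data generator so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    Rsamtools,
    rtracklayer,
    EBImage,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
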