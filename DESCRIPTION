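Package: synphylo
Title: Synteny-Based Phylostratigraphy and Classification of Young Genes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies focal-species query genes against related target
    genomes by restricting homology search to syntenically mapped intervals.
    Each query x target pair receives one of thirteen homology classes
    (amino-acid-level, nucleotide-only, or unknown with a diagnosed cause)
    via a configurable first-affirmative decision tree backed by
    Smith-Waterman alignment with an extreme-value significance model.
    Per-species classes are collapsed across a rooted species tree into UNA
    vectors and synteny-based phylostrata, separating well-supported de novo
    gene candidates from genes that are missing for technical reasons.
    Includes a seeded generator of miniature genome fixtures with planted
    evolutionary scenarios so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, ComparativeGenomics, Alignment,
    SequenceMatching
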