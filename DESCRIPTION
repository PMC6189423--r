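Package: synshrink
Title: Simulation and Comparative Analysis of Genome-Size Reduction After
    Chromosomal Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator of recombination-driven genome-size reduction
    following chromosomal inversions and relocations, together with the
    comparative-genomics toolkit needed to analyse a diverged genome pair:
    homolog pairing and collinear synteny-block chaining, inversion detection
    and syntenic-block size ratios, gene-density partition tracks and Marey-map
    recombination profiles, transposable-element counts and composition tables,
    deletion-mechanism forensics (unaligned-segment extraction, flanking-repeat
    classification, solo-LTR inventories), and a relative rate-of-reduction
    estimator. Synthetic genome pairs with full event-level ground truth are
    generated and serialized to FASTA/GFF3/TSV so every stage of the pipeline
    can be validated against planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    BiocGenerics,
    IRanges,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
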