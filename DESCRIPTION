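Package: u12splice
Title: U12-Type Intron Splicing Efficiency and Retention from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects minor-spliceosome (U12-type intron) splicing deficiency
    from aligned RNA-seq. Quantifies split reads across U12-type splice
    junctions normalized to two U2-type reference junctions of the same gene
    and to per-gene FPKM, measures intron retention from intron-body read
    depth, discards genes with high control variability, and ranks genes
    whose case samples deviate by more than a z-score threshold in at least
    two of the four metrics. Also detects and classifies aberrant processing
    events at U12-type introns (cryptic U2-type splice-site activation and
    exon skipping) and quantifies their abundance relative to canonical
    splicing. Includes a seeded spliced-read simulator with a known
    per-molecule truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
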