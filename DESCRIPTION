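Package: chlamycomp
Title: Comparative Genomic Audits and Conservation Landscapes for Chlamydomonas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for reference-anchored comparative genomics of
    Chlamydomonas and relatives: auditing of gene-model coding potential
    (aggregation of per-exon coding-potential scores, the pi0D/pi4D diversity
    ratio, a mutation-bias-adjusted codon adaptation index, and Kozak-context
    information scoring), conservation-landscape analysis over a multi-species
    whole-genome alignment (per-class alignability, four-fold degenerate site
    extraction, ultraconserved-element scanning, conserved-element overlap
    tables, intron-length conservation bins), and genome screens (telomere
    motifs, terminal repeat features, windowed element density, repeat-overlap
    gene filtering, gene-family expansion calls). A seeded synthetic-data
    generator emulates every input with a ground-truth manifest so the whole
    pipeline is testable against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    seqinr
Config/testthat/edition: 3
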