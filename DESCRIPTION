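Package: txblocks
Title: Reference-Guided Transcript Assembly from Strand-Specific Coverage Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transcript boundaries, untranslated regions (UTRs) and
    non-coding transcripts in intron-poor genomes (yeasts, prokaryotes) from
    strand-specific single-end RNA-seq alignments. Overlapping reads are joined
    into strand-specific coverage blocks; gap-size and coverage-ratio statistics
    learned from blocks matching annotated genes drive an adaptive
    two-standard-deviation rule that absorbs intergenic blocks; spliced reads
    call introns under a spliced/unspliced ratio filter; low-coverage transcript
    tails are trimmed and polycistronic candidates validated by coverage
    continuity. Downstream layers classify antisense (SAUT) and intergenic (SUT)
    non-coding transcripts, compare UTR variability across strains, and
    intersect polycistronic calls across growth conditions. A synthetic-data
    generator emulates the characteristic pathologies of strand-specific
    short-read coverage (hotspots, zero-coverage gaps, background noise, poly-A
    read loss) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
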