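Package: woodsplice
Title: Alternative Splicing Events, Functional Impact and Cross-Species
    Conservation in Wood-Forming Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies alternative splicing (AS) events from
    transcript annotations by pairwise splice-chain comparison (intron
    retention, alternative acceptor/donor, exon skipping, alternative
    position), applies FPKM-based expression filters, annotates the
    functional impact of each event (mRNA feature localization via
    longest-ORF translation, reading-frame disruption, protein domain
    modification, gain and loss, Fisher exact domain enrichment), and
    identifies AS events conserved between two species through
    reciprocal-best-hit orthology and translated local alignment of
    exonic sequences flanking alternative introns. Includes a synthetic
    two-species data generator with planted ground truth so every stage
    of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
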