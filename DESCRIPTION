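Package: plastdiv
Title: Comparative Divergence Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastomes:
    detection of the quadripartite structure (LSC/SSC/inverted repeats) and
    single-copy/IR junction comparison, genome summarization, stepwise
    sliding-window scans of nucleotide diversity (Pi), GC content and gap
    proportion with divergence-hotspot ranking and correlation tests,
    region classification (exon/intron/intergenic spacer) with per-region
    divergence and parsimony-informative character counts, gap-filtered
    supermatrix construction with RAxML-style partitions, and
    Nei-Gojobori (1986) counting estimates of synonymous and nonsynonymous
    substitution rates per gene and per functional group. A plastome
    simulator with a replayable ground-truth registry (planted inverted
    repeats, region-specific substitution rates, intron/spacer-only
    indels, omega-controlled coding evolution) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    seqinr
Config/testthat/edition: 3
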