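Package: mitornmp
Title: Analysis of Ribonucleotides Embedded in Circular Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-nucleotide maps of ribonucleoside
    monophosphates (rNMPs) embedded in a circular mitochondrial genome, as
    produced by ribose-seq-style capture protocols. Provides circular-genome
    coordinate arithmetic, post-alignment filtering (circular-origin recovery,
    reference-mismatch removal, restriction-site noise removal), normalized
    embedment metrics (probability per base, enrichment factor, moving
    averages), detection of rNMP-enriched zones in 200-nt bins and of
    single-nucleotide hotspots across libraries, background-normalized
    composition and dinucleotide/trinucleotide context frequencies,
    strand-bias contribution decomposition, gene-level frequency tables with
    size-correlation analyses and random-library controls, control-region and
    7S-DNA profiling, and a seeded synthetic-data generator with truth tables
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    data.table,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
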