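Package: repascan
Title: Purine-Rich Regulatory Elements Between the Polypyrimidine Tract
    and the 3' AG of Acceptor Splice Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide identification and characterization of purine-rich
    regulatory elements (REPA), in particular G tracts, located between the
    polypyrimidine tract and the 3' AG of acceptor splice sites. Derives
    introns and strand-aware acceptor windows from a genome FASTA plus
    GTF/GFF3 annotation, flags purine-rich acceptors, detects G tracts and
    positional nucleotide profiles, scores acceptor strength with a trainable
    maximum-entropy sequence model, classifies alternative-splicing events
    from multi-transcript annotation, computes hypergeometric and Fisher
    enrichment statistics, and calls the evolutionary clade of emergence of
    G tracts from ortholog presence/absence matrices. Seeded synthetic-data
    generators make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
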