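Package: snoKturn
Title: Annotation and Functional Classification of Box C/D snoRNA Kink-Turn Motifs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates the conserved box C, D, C' and D' motifs of box C/D small
    nucleolar RNAs, maps the kink-turn (k-turn) coordinate frame onto annotated
    motifs, evaluates the sequence features (tandem sheared G:A pairs, stem I
    integrity, consensus identity) that determine whether an internal box C'/D'
    element can recruit the k-turn binding proteins Snu13 and L7Ae, and
    classifies motifs into functional categories with census statistics over
    snoRNA sets. Also predicts ribose 2'-O-methylation target sites on substrate
    RNAs via the guide-duplex fifth-nucleotide rule, computes theoretical
    average masses of RNA-protein assemblies for stoichiometry ranking against
    observed masses, and generates labelled synthetic snoRNA benchmarks with
    planted motifs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
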