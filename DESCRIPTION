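Package: rmsep
Title: Detection of Solitary Restriction Endonucleases and Separated
    Restriction-Modification Systems in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("rmsep", "maintainers", email = "rmsep@example.org",
           role = c("aut", "cre"))
Description: A comparative-genomics pipeline for classifying restriction
    endonuclease (RE) genes that lack a co-localized DNA methyltransferase
    (MTase) partner. Implements completeness classification of annotated
    restriction-modification (R-M) systems, a 4 kb vicinity scan for
    MTase-like open reading frames, a length-based truncation filter,
    best-bidirectional-hit orthology with role-specific identity and
    coverage thresholds, transfer of partner MTases through orthologous
    complete systems to predict "separated" R-M systems whose genes lie
    more than 4 kb apart, a screen against methyl-directed (Type IV) REs
    with single-linkage clustering, progressive alignment, neighbor-joining
    trees and bootstrap support, and a 20 kb mobile-genetic-element
    neighborhood scan. Ships a deterministic synthetic genome cohort
    generator with planted ground truth so every stage is testable without
    external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
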