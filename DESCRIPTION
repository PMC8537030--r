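Package: plastomat
Title: Coordination of Plastid Transcript Maturation from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of the coordination between plastid RNA maturation
    events (C-to-U editing and group-II intron splicing) from long,
    strand-oriented cDNA reads. Each read is annotated as mature, immature
    or not-read at every catalogued event; pairwise dependencies are tested
    with Fisher exact tests under replicate-consensus FDR control; a
    preferred chronology of maturation is inferred from the relative
    abundance of maturation intermediates; editing and splicing rates,
    strand-specific coverage profiles and virtual Northern blots summarise
    the transcript population. A kinetic read simulator with plantable
    dependencies, ordered rates, nanopore-like errors and long-transcript
    capture bias makes the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    igraph,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
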