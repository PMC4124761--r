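Package: smallRNAsig
Title: Small RNA-Seq Profiling with Hierarchical ncRNA Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline: adapter
    trimming and clean-read filtering, read collapsing into tags,
    perfect-match double-stranded genome matching with full multi-hit
    reporting, priority-ordered annotation into miRNA, structural RNA,
    piRNA and endo-siRNA classes, and class-specific quantification
    (RPM-normalised miRNA signatures and sample clustering, hit-weighted
    piRNA genome landscapes with repeat-family enrichment, and a
    three-criterion endo-siRNA screen). A bundled synthetic-data generator
    produces toy genomes, annotation tracks and ground-truthed FASTQ read
    sets so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
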