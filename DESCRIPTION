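Package: loop4c
Title: Allele-Specific 4C-seq Interaction Scoring and smFISH Transcription Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-level analysis of circular chromosome conformation capture
    (4C-seq) experiments and single-molecule RNA FISH image stacks, built around
    an allele-specific dissection of the mouse Sox2 locus. Provides in-silico
    restriction digestion and fragment-end maps (including engineered-allele
    coordinate maps after deletions and insertions), read demultiplexing and
    fragment-end assignment, deletion-aware running-mean profiles, interaction
    calling against a monotonic distance-decay background, quantile-normalized
    region interaction scores with condition comparisons and TAD-leakiness
    quantification, spot-based mRNA and transcription-site counting, and seeded
    generators of synthetic 4C libraries and smFISH stacks with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    limma,
    EBImage,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
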