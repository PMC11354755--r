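Package: rtindex
Title: Terminator Readthrough Analysis of Strand-Specific Nascent RNA Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcription-termination defects genome-wide from
    strand-specific nascent-RNA (GRO-seq) 3'-end coverage. Computes a
    per-gene readthrough index (RTI) around annotated poly(A) sites,
    applies neighbor-distance, gene-length and expression filters, calls
    differential readthrough between genotypes with one-sided Welch
    t-tests, and builds CDS-normalized metagene profiles and
    readthrough-ordered heat-map matrices. Companion modules quantify
    bait-normalized spectral abundance factors (BNSAF) from
    affinity-purification mass-spectrometry spectral counts, and normalize
    ChIP occupancy and transcription run-on (TRO) signals. A synthetic-data
    generator with known ground truth emulates strand-specific nascent
    coverage with parametric terminator readthrough so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    grDevices,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    rlang,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
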