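Package: segquant
Title: Transcript Abundance from RNA-seq by Mappability-Based
    Segmentation and Joint Poisson Likelihood
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies transcript expression from transcriptome-aligned
    RNA-seq reads without probabilistic read assignment. The transcriptome
    is partitioned into "segments" -- groups of read-length substrings
    (virtual reads) shared by the same multiset of transcripts -- whose
    lengths encode mappability exactly. Aligned reads are filtered to their
    best-mismatch alignments, counted per segment, and transcript
    abundances are obtained by maximizing a joint Poisson likelihood over
    each sequence-sharing set of transcripts, yielding FPKM, TPM and
    inferred read counts. Includes a versioned transcriptome index, a
    SAM/BAM counting stage, a seeded read simulator with ground truth, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    optparse,
    BiocGenerics,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
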