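Package: circkit
Title: Back-Splice Junction Analysis and Translation Evidence for Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for downstream analysis of circular RNAs (circRNAs) after
    detection. Builds pseudo-circular (doubled) back-splice-junction reference
    sequences so that linear aligners can place reads across the junction,
    calls translated circRNAs from ribosome-profiling alignments using an
    rRNA/linear-transcript subtraction filter and a junction-spanning read
    threshold, classifies circRNAs into seven junction-position categories
    against a gene annotation, profiles splice-signal dinucleotides, length
    and chromosome distributions and genomic GC content, and detects
    reverse-complementary stem-loop pairings in circRNA flanks by local
    alignment. Includes a deterministic synthetic-data generator producing
    self-consistent genome, annotation, circRNA and alignment fixtures, thin
    plot renderers over the computed tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
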