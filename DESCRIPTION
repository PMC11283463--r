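Package: abcdPCR
Title: Drop-Off Digital PCR Quantification of Mutation Scars at AID Break Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying somatic mutation scars at AID (activation-induced
    cytidine deaminase) break clusters from multiplexed drop-off digital PCR and
    amplicon sequencing. Implements chamber classification from multi-channel
    fluorescence, Poisson partition inference of copies per microliter with
    Wilson-transformed confidence intervals, per-probe drop-off estimation by a
    difference estimator and by Moebius inversion over channel-subset negativity
    patterns, group comparisons with Dunnett-style multiplicity adjustment,
    per-position indel profiling from aligned amplicon reads, AID hotspot motif
    scanning (WRC/RCG/WGCW, CpG proximity, cryptic RSS), and a seeded synthetic
    assay generator producing ground-truthed chamber tables and aligned reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
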