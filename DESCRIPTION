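Package: screads
Title: Simulation of Single-Cell RNA-Seq and ATAC-Seq Sequencing Reads with
    Ground Truths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns from a real (or synthetically generated) set of aligned,
    barcoded single-cell sequencing reads and emits realistic synthetic
    scRNA-seq or scATAC-seq reads in FASTQ/SAM form together with their
    ground truths: a UMI count matrix for scRNA-seq and ground-truth
    peak/non-peak region sets for scATAC-seq.  Counts for synthetic cells
    are drawn from a per-cluster negative-binomial marginal model coupled
    by a Gaussian copula; read positions are resampled from the real reads
    with small uniform shifts, fragment sizes of paired-end reads are
    preserved exactly, and per-position substitution errors estimated from
    the real reads are injected into the synthetic sequences.  Supports
    user-designed open-chromatin regions, varying cell numbers and
    sequencing depths, and ships a fixture generator so the full pipeline
    runs on toy data with planted ground truths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
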