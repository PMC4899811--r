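Package: gmekit
Title: Global Microsatellite Enrichment Bait Design and Unmapped-Read
    Repeat Discovery
Version: 0.1.0
Authors@R:
    person("GME", "Maintainers", email = "gmekit@example.org", role = c("aut", "cre"))
Description: Tools for reference-independent discovery of microsatellite
    (short tandem repeat, MST) loci. Designs a complete hybridization-capture
    bait set in which every primitive 1-6 base repeat motif family is
    represented on a 120 nt oligo built from four 30 nt tandem-motif segments
    balanced toward 40% G+C with low hairpin potential. Implements the
    downstream analysis of unmapped sequencing reads: sliding-window quality
    trimming and N filtering, period 1-6 tandem-repeat detection with Tandem
    Repeat Finder scoring parameters, classification of assembled contigs as
    known or novel against reference sequence sets, clustering of novel
    contigs observed in two or more samples into concordant groups with
    consensus sequences, k-mer family read-depth tables and motif-class
    enrichment statistics, and matching of contigs and putative cDNAs to
    RNA-seq-like reads. A synthetic-data module (genome and read simulator,
    naive mapper, greedy assembler emitting Velvet-style contig identifiers)
    makes the whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    BiocGenerics,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
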