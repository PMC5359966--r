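Package: mirtally
Title: Reference-Based Quantification of miRNAs and isomiRs from Small-RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds an extended, clustered, delimiter-encoded miRNA alignment
    reference from miRBase-style mature and hairpin FASTA files, and quantifies
    known miRNAs and their 5'/3' isomiRs from multi-sample single-end small-RNA
    sequencing data. Reads are adapter-trimmed, length-filtered, and collapsed
    into unique sequences within and across samples before strand-aware
    (sense-only) alignment with a bounded number of mismatches. Unique reads are
    annotated sequentially against miRNA, hairpin, small RNA and mRNA
    references; mismatch-carrying miRNA hits can be invalidated by perfect
    remapping to a reference genome; sporadic background reads are removed by a
    cross-sample noise filter. Outputs include miRNA and isomiR count matrices
    with mismatch-only companions, RPM normalization, and per-sample QC metrics
    (annotation breakdown, read redundancy, length and end-offset
    distributions). A deterministic synthetic-data generator emulating
    miRBase-like reference structures and stranded isomiR reads supports
    end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
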