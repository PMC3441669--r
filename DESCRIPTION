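Package: srnapipe
Title: Small RNA Sequencing Profiling with Hairpin miRNA Discovery and
    Digital Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for
    two-condition experiments: adapter and contaminant cleaning of raw
    reads with exact accounting, zero-mismatch mapping of 18-30 nt tags to
    both genome strands, priority-rule annotation against structural RNA,
    exon and intron intervals, siRNA duplex detection via the 2-nt
    3' overhang criterion, novel miRNA prediction from hairpin precursor
    folding under Mireap-style acceptance thresholds, and Audic-Claverie
    digital differential expression with tags-per-million normalization.
    Includes a synthetic-data generator that plants ground-truthed
    miRNA hairpins, siRNA duplexes and structural RNA loci in a toy
    genome and simulates condition-dependent read sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
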