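Package: csfscna
Title: Somatic Copy Number Profiling of Cell-Free DNA from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bin-based depth-of-coverage profiling of shallow whole-genome
    sequencing of cell-free DNA (cfDNA), as used for liquid biopsy of
    cerebrospinal fluid in neuro-oncology. Read-pair counts in fixed genomic
    windows (default 5.5 Mbp) are corrected for GC content and mappability,
    median-normalized and log2-transformed; bins beyond +/-0.1 are called
    aberrant and summarized into three diagnostic metrics: the chromosomal
    number instability (CNI) score, the aberrant-bin count with a >=5-bin
    positivity rule, and the tumor-cfDNA fraction score. Includes paired-sample
    concordance analysis, rule-based diagnostic flags for WHO-relevant copy
    number patterns (1p/19q codeletion, chromosome 7 gain with 10 loss,
    CDKN2A/B homozygous deletion, 6q loss, focal amplifications), and a
    synthetic-data generator that simulates overdispersed bin counts for
    tumor/normal cfDNA mixtures over segment-level copy-number profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
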