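Package: strandqc
Title: Quality Control Metrics for Strand-Specific RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-library quality-control metrics for strand-specific
    (dUTP/UNG) paired-end RNA-seq libraries from coordinate-level alignment
    records: strand-specificity from reads spanning annotated exon-exon
    junctions, read-category percentages (exonic/intronic/intergenic, rRNA,
    mitochondrial), gene-level expression and detection, 5'-to-3' transcript
    coverage bias, base error rates by mismatch counting, spike-in
    dose-response and error rates, insert-size estimation from mitochondrial
    alignments, seeded pair-preserving down-sampling, and duplicate marking.
    Includes a deterministic synthetic-data generator that emits toy
    references, annotation, spike-in panels and spliced paired alignment
    records with known ground truth, so every metric is validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
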