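Package: srnaregen
Title: Small RNA Profiling of Planarian Head Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a small RNA sequencing analysis
    pipeline for head regeneration time courses in the planarian Dugesia
    japonica. Provides a synthetic-data generator that plants miRNA hairpins,
    tRNAs, rRNAs, mRNAs, repeats and piRNA clusters in a toy genome and emits
    truth-labelled FASTQ libraries; raw-read quality filtering with per-rule
    accounting; ungapped genome mapping with best-hit filtering; a
    precedence-cascade small RNA classifier with tRNA-fragment typing and
    repeat orientation accounting; de novo miRNA locus discovery with
    hairpin-duplex criteria and homology naming; piRNA diagnostics (5' uridine
    bias, ping-pong overlap Z-scores, ping-pong length matrices, cluster
    prediction and merging); per-class reads-per-million expression matrices
    with average-linkage/Pearson hierarchical clustering; and downstream
    seed-based miRNA target scanning, chi-square GO term enrichment with
    Bonferroni correction, and knockdown phenotype scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
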