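Package: bsmeth
Title: Sliding-Window Analysis of Whole-Genome Bisulfite Sequencing Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of whole-genome bisulfite sequencing (WGBS)
    methylomes between two pooled groups: cytosine context classification
    (CpG/CHG/CHH) from a reference genome, per-site and sliding-window
    methylation-level estimation with lambda spike-in non-conversion
    correction, genome-wide context summaries, 9-mer sequence-preference
    tabulation, functional-region and 20-bin metagene profiling,
    differentially methylated region (DMR) calling by windowed Fisher exact
    tests with Benjamini-Hochberg FDR and coverage/fold-change filters,
    gene assignment (DMGs), and association of DMGs with differentially
    expressed genes. Includes a synthetic-data generator with planted
    effects and known ground truth for end-to-end validation, plus FASTQ
    read-quality filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
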