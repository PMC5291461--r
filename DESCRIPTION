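Package: senemeth
Title: Integrative Methylome and Transcriptome Analysis of Replicative
    Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for array-based DNA methylation and gene
    expression profiling of replicative senescence in cultured fibroblasts.
    Implements beta-value methylation calling with delta-beta thresholds and
    detection p-value filtering, sequential (stepwise) change classification
    across a passage series, summaries over CpG-context and gene-feature
    subcategories, sequence-based CpG-island promoter classification (GC
    content and observed/expected CpG ratio), integration of differential
    methylation with expression of the nearest gene within a fixed distance
    of the transcription start site, and identification of genes whose
    up-regulation is supported by two or more miRNAs that are down-regulated
    with hypermethylated promoters.  A synthetic-data module generates every
    input the pipeline consumes, with planted ground truth, so the whole
    analysis is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
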