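Package: tfinet
Title: TFI Transcript Classification and Transcription-Factor Binding
    Networks from Knockdown Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers TBP family-insensitive (TFI) transcripts from
    multi-condition knockdown, developmental-stage and alpha-amanitin
    expression data, and embeds them in a transcription-factor binding
    network.  Provides replicate-consistent Wilcoxon signed-rank change
    calls on probe-level data, a median-of-ratios negative-binomial
    differential expression test, hypergeometric over-representation with
    Benjamini-Hochberg FDR control, k-means clustering of expression
    ratios under Pearson correlation distance, ChIP peak filtering
    against input coverage, basal-plus-extension regulatory-domain
    assignment of peaks to genes, and co-binding, indegree and
    fully-connected-triad statistics on the resulting directed network.
    A synthetic-data generator emulates the full experimental design with
    planted ground truth so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
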