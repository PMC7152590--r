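Package: stressmem
Title: Nutrient-Stress Transcriptomics and Stress-Memory Gene Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for multi-timepoint nutrient-stress RNA-seq
    analysis in a two-tissue, two-stress (iron and phosphate deficiency),
    four-timepoint design with recovery and repeated-stress exposures.
    Provides median-of-ratios library-size normalization, MDS-based replicate
    quality control, a negative-binomial exact test for differential
    expression with Benjamini-Hochberg correction, Fisher's-exact
    overrepresentation of Gene Ontology terms and transcription-factor
    families with Bonferroni correction, GO-percentage profile clustering,
    two-class transcriptional stress-memory gene identification, QTL
    interval candidate-gene overlay, and a synthetic count-data generator
    with planted ground truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
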