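Package: qtlome
Title: Quality Control, Density and Enrichment Analysis of Livestock QTL Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the QTLome of livestock species from
    AnimalQTLdb-style QTL annotation files: a quality-control cascade that
    removes anomalous, over-long and duplicated annotations and merges
    same-study/same-trait clusters with a densest-window fallback and size
    standardization; fixed-width genome windowing with QTL, gene, SNP, study
    and trait counts; Pearson correlations with permutation p-values at
    chromosome and window scales; exact binomial, hypergeometric and
    resampling-based enrichment tests with Benjamini-Hochberg adjustment; and
    a synthetic QTLome generator with planted hotspots, duplicates and
    coordinate anomalies so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
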