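Package: interomics
Title: Multi-Omics Integration of Chromatin, Transcriptome and Proteome
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for integrating time-course multi-omics
    experiments (ATAC-seq open-chromatin calls, RNA-seq and proteomics
    differential tables and expression matrices). Implements rank-rank
    hypergeometric overlap (RRHO) comparison of ranked gene signatures
    with Benjamini-Yekutieli correction, linkage of open chromatin
    regions to genes by TSS windows with frequency, intensity and
    enrichment statistics, weighted co-expression module detection with
    topological overlap and resampling-based module quality Z-scores,
    cross-layer (mRNA vs protein) module overlap testing, hypergeometric
    connector enrichment on background protein-protein interaction and
    regulatory networks, and clique-based overlapping community
    detection. A synthetic-data generator with planted structure
    provides ground-truth recovery tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
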