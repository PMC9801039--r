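Package: DEMcluster
Title: Co-Dysregulation of Genomically Clustered miRNAs Across Cancers
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of whether genomically clustered microRNAs are
    dysregulated together across cancer types. Provides readers for
    differentially expressed miRNA (DEM) call tables, miRBase-style GFF3
    annotation and alias tables; identification of miRNA clusters from
    precursor coordinates; a per-cluster homogeneity statistic with a
    marginal-preserving permutation null; a per-cancer log-odds (LOD)
    enrichment score for clustered miRNAs; vote-counting consistency
    scores for meta-profiling; and a synthetic DEM generator with planted
    co-direction signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'clusters.R'
    'enrichment.R'
    'homogeneity.R'
    'io.R'
    'meta.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
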