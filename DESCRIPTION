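Package: chipea
Title: ChIP-Seq Enrichment Analysis for Drug Mode-of-Action Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies transcription factors whose experimentally mapped
    binding sites (ChIP-seq peak calls) are enriched near the transcription
    start sites of chemically up-regulated versus down-regulated genes,
    using a two-tailed Fisher's exact test on gene-level peak overlaps
    within TSS-flank windows. Enriched factors are linked to diseases via
    protein-disease associations to predict chemical-disease relationships,
    which are benchmarked (per-chemical and global AUROC/AUPR) against
    interaction standards alongside a transcription-factor-free baseline
    that cross-tabulates differentially expressed gene labels. Ships a
    deterministic synthetic-data generator with planted ground truth so the
    whole pipeline runs without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'chipea-package.R'
    'AllClasses.R'
    'formats-io.R'
    'genome-windows.R'
    'chipea-core.R'
    'disease-linkage.R'
    'benchmark-eval.R'
    'deg-baseline.R'
    'synthetic-fixtures.R'
    'pipeline.R'
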