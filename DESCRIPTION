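Package: dmrkit
Title: Differential CpG Methylation, DMR Calling, and Regulatory Enrichment
    for Bisulfite Count Data
Version: 0.1.0
Authors@R:
    person("dmrkit", "developers", email = "dmrkit@example.org",
           role = c("aut", "cre"))
Description: A pipeline for whole-genome bisulfite sequencing count tables:
    per-CpG differential methylation testing (pooled Fisher exact or
    replicate-aware logistic likelihood-ratio test), Benjamini-Hochberg
    correction, chaining of differentially methylated CpGs into regions,
    genomic-feature and TSS-distance contextualization with odds-ratio
    enrichment statistics, coverage-matched background sampling, PWM and
    k-mer motif enrichment in windows around differentially methylated
    CpGs, high-confidence antisense/intergenic lncRNA classification, and
    ortholog-mapped gene-set over-representation. Ships a synthetic-data
    generator (beta-binomial methylation counts with planted DMRs, planted
    motif instances, and planted differentially expressed gene sets) so
    every stage can be exercised against known ground truth without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    rtracklayer,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
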