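Package: dmrscan
Title: Running-Sum DMR Calling and Permutation-Calibrated Differential
    Methylation and Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-group reduced representation bisulfite
    sequencing (RRBS) and companion RNA-seq studies. Implements per-CpG
    differential methylation via a beta-binomial Wald test with
    coverage-weighted dispersion shrinkage, a running-sum caller for
    differentially methylated regions driven by per-site one-way ANOVA
    f-statistics, exhaustive and random group-label permutation with
    empirical false discovery rates, transcription start site (TSS)
    window methylation summaries with principal component segregation
    tests, genomic-feature and TSS-distance enrichment of differential
    methylation, directional hypergeometric gene-set enrichment with
    expression-matched backgrounds, and a synthetic-data generator that
    emulates the bimodal CpG methylation landscape, RRBS coverage
    structure and planted effects needed to validate every stage against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
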