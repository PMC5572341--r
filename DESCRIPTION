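Package: cnvherd
Title: Population Analysis of SNP-Array Copy Number Variation in Cattle Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of copy number variation (CNV)
    called from SNP genotyping arrays. Starting from per-sample CNV calls in the
    PennCNV text dialect and probe-level log R ratio (LRR) / B-allele frequency
    (BAF) matrices, the package computes population B-allele frequencies, applies
    GC-wave adjustment and per-sample quality control, merges calls across samples
    into CNV regions (CNVRs), compares per-sample CNV burden between breed groups
    (Kruskal-Wallis / ANOVA with Bonferroni-corrected post hoc tests), scans for
    population-differentiated regions with the V_st statistic including a
    sex-dosage artifact filter, clusters samples by Jaccard distance on CNVR
    presence/absence with UPGMA, and accounts overlaps against reference interval
    sets such as genes and segmental duplications. A synthetic-cohort generator
    with known truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
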