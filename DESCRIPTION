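Package: ChIPRx
Title: Spike-In Normalized Comparative ChIP-seq Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of ChIP-seq experiments calibrated with
    exogenous spike-in chromatin (ChIP-Rx). Partitions aligned fragments from
    a combined two-organism reference by chromosome namespace, derives
    per-sample spike-in normalization factors, builds coverage tracks and
    expression-stratified metagene profiles in reads per kilobase per ten
    million mapped reads, classifies enrichment peaks across conditions and
    replicate clones, annotates peaks against genomic feature sets with
    binary co-localization clustering, and quantifies differential histone
    mark retention with grouped Student's t statistics. Includes a seeded
    synthetic-data generator that emulates two-organism fragment mixtures
    with planted enrichment domains, condition-level global mark reduction,
    and fixed-depth resampling, so every stage can be validated against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), GenomicRanges
Imports: methods, stats, utils, grDevices, graphics, S4Vectors, IRanges,
    GenomeInfoDb, jsonlite, yaml
Suggests: testthat (>= 3.0.0), mclust
Config/testthat/edition: 3
biocViews: ChIPSeq, Epigenetics, Normalization, Coverage, PeakDetection
RoxygenNote: 7.3.3
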