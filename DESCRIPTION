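Package: epilineage
Title: Lineage Reconstruction from Nucleosome Occupancy and Histone-Mark
    Signal in Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative epigenomic pipeline for neural cell types:
    TSS-anchored nucleosome occupancy profiling from MNase-seq, RPM/RPKM
    quantification of histone-modification ChIP-seq signal in promoters and
    enhancers, two-mark chromatin-state classification with state-transition
    flows, Poisson sliding-window enhancer calling with nearest-gene target
    assignment, ROC evaluation of histone marks as predictors of gene
    activity, and hierarchical lineage reconstruction from Z-scored
    regulatory signal matrices. Includes a synthetic-data generator with a
    planted lineage tree (NSC, GNP, glia, neuron) so that every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
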