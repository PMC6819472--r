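Package: imprintr
Title: Discovery and Classification of Genomic Imprints from Reciprocal
    Hybrid Multi-Omic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An allelic inference pipeline for discovering and classifying
    genomic imprints in reciprocal hybrid mouse embryos. Assigns sequencing
    reads to parental genomes from strain-discriminating SNPs (including a
    two-pass scheme for admixed maternal genomes), tests regions for allelic
    imbalance with a replicate-aware beta-binomial likelihood-ratio test,
    classifies peaks into strain-specific, canonical imprinted and
    non-canonical imprinted classes via reciprocal-cross and maternal
    DNA-methylation-knockout contrasts, identifies transcriptionally active
    ERVK LTR promoters from spliced RNA evidence, computes genomic feature
    enrichment statistics, and calls allele-resolved differentially
    methylated regions across developmental stages. A synthetic-data
    generator plants known imprinting architecture so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
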