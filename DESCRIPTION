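Package: ergstrata
Title: Stratified Multi-Omics Comparison of ERG Fusion-Defined Prostate Cancer Subtypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies prostate tumor cohorts into ERG fusion-positive and
    fusion-negative groups from dual fusion-call evidence and compares the
    groups across omics layers: clinical association tables with an
    expected-count driven chi-squared/Fisher chooser, gene fusion and somatic
    mutation frequencies, 10 kb genome-binned somatic copy-number alteration
    frequencies with cytoband and arm summaries, direction-aware tumor
    suppressor/oncogene SCNA classification, a representative-gene signature
    with sample coverage, differential expression with group overlap, a
    five-step promoter hypermethylation filter cascade, and pathway-level
    alteration frequencies. A seeded synthetic-cohort generator emulates the
    statistical structure of such cohorts so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: CopyNumberVariation, GeneFusionDetection, DifferentialExpression,
    DNAMethylation, Survival, Software
RoxygenNote: 7.3.3
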