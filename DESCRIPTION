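Package: dendrogwas
Title: Dendro-Genomic Analysis of Drought Response in Conifer Provenance Trials
Version: 0.1.0
Authors@R: person("Forest Genetics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking dendroclimatology, quantitative
    genetics and genome-wide association for long-lived trees grown in common
    gardens. Computes the standardized precipitation index (SPI) from station
    climate records, detects and classifies drought events, derives the Lloret
    drought response indicators (resistance, recovery, resilience, relative
    resilience) from tree-ring series, estimates repeatability of drought
    response by REML variance components, builds a centered-IBS genomic
    kinship matrix, and scans biallelic SNPs against trait tables with an
    exact per-marker mixed linear model including admixture covariates and a
    polygenic kinship effect (MLM+Q+K). A deterministic synthetic-data
    generator with known ground truth supports closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    VariantAnnotation,
    SummarizedExperiment,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
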