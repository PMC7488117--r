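Package: gtconcord
Title: Genotype Concordance Between BeadChip and Whole-Genome Sequencing
    Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes genotype calls from Illumina BeadChip microarrays
    (GenomeStudio final reports) and whole-genome sequencing (VCF) into
    paired per-site calls, builds 6x6 diploid genotype-class confusion
    matrices, and computes concordance quality metrics (genotype
    concordance, non-reference concordance and sensitivity, weighted
    precision and sensitivity, mean per-class specificity and accuracy)
    via per-class dimensionality reduction. Maps discordance along the
    genome (per-chromosome fractions, neighbor-distance pairs with 2-D
    Gaussian kernel density estimates), selects compact sliding-window
    regions of discordant variants suitable for Sanger validation,
    adjudicates three-way BeadChip/WGS/Sanger comparisons with
    Sanger-as-truth metrics, and ships a seeded synthetic-data generator
    (Hardy-Weinberg genotypes, platform miscall processes, BeadChip
    intensity clusters) so the whole pipeline runs without access to
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
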