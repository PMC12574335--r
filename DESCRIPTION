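Package: rootqg
Title: Image-Based Root Shape Phenotyping and Quantitative Genetics for
    Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for quantitative genetics of storage-root
    shape in multi-environment diversity panels. Extracts six shape traits
    (digital biomass, length, maximum width, width at half length,
    log length-to-width ratio, tip angle, and a contour principal-component
    score) from binary root-silhouette images; fits the multi-environment
    mixed linear model (genotype, environment, genotype-by-environment,
    block-in-environment, plot, residual) to obtain BLUEs, variance
    components and Cullis broad-sense heritability; infers population
    structure (LD pruning, PCA, admixture EM with cross-validated selection
    of the number of populations, Nei 1972 distances, neighbor-joining
    trees, pairwise Fst); runs kinship mixed-linear-model genome-wide
    association scans (K and K-LOCO) with Bonferroni thresholds, inflation
    diagnostics, per-marker variance explained and consensus QTL calling;
    performs RR-BLUP genomic prediction with cross-validated accuracy; and
    windows candidate genes around QTL with Fisher-exact GO enrichment. A
    synthetic-data generator (root silhouettes, Balding-Nichols structured
    genotypes, phenotypes with configurable variance components and causal
    QTL) provides ground truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    lme4,
    ape,
    vcfR,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
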