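Package: samgwas
Title: Parabolic Morphometrics and Mixed-Model GWAS for Shoot Apical
    Meristem Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end quantitative pipeline from microscopic shoot
    apical meristem (SAM) images to genotype-phenotype associations.
    Fits parabolic models to SAM contours and derives the full set of
    shape microphenotypes (height, radius, midsection area, volume,
    surface area, arc length), computes per-genotype BLUP phenotypes and
    entry-mean repeatability across replicated trials, builds homozygous
    genotype matrices from quality-trimmed reads and pileup SNP calls
    with consensus merging and MAF/missingness filters, runs a unified
    mixed linear model association scan with VanRaden kinship and
    principal-component covariates, calls trait-associated SNPs at a
    Bonferroni threshold with candidate-gene window mapping and
    ALT-allele burden analysis, and quantifies SAM cell number and cell
    size from nuclei segmentation and Voronoi cell lattices. Seeded
    synthetic-data generators produce every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    lme4,
    EBImage,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
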