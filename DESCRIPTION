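Package: salmofat
Title: Quantitative Genetics and Transcriptome Association of Liver Fat in Farmed Salmon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic and transcriptomic analysis of liver fat
    variation in farmed Atlantic salmon populations: SNP array quality
    control (call rate, minor allele frequency, Hardy-Weinberg filters),
    VanRaden genomic relationship matrices and their principal components,
    univariate and bivariate GREML estimation of variance components,
    heritabilities and genetic correlations by average-information REML,
    mixed-linear-model genome-wide association with leave-one-chromosome-out
    relationship matrices, Bonferroni significance thresholds and the
    genomic inflation factor, candidate-gene window scans around top SNPs,
    FPKM normalisation and per-gene trait-expression linear mixed models,
    and Yates-corrected chi-square term enrichment.  A pedigree-based
    gene-dropping simulator generates genotypes, multi-trait polygenic
    phenotypes, trait-coupled expression matrices and compositional
    fatty-acid panels with which every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
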