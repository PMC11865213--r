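#' Default trait panel for the phenotype simulator
#'
#' One row per simulated trait with its population mean, additive genetic
#' variance, residual variance and (centred) sex effect.  The liver-fat row
#' uses the study calibration of 2.59 genetic and 4.19 residual variance
#' (phenotypic SD 2.6 at a mean of 7.6 % fat); the remaining traits are
#' parameterised from their phenotypic SDs and heritabilities (muscle fat
#' 0.43, body weight 0.58, liver score 0.28, HSI 0.19, viscera score 0.28).
#' Score traits are generated on a continuous 1-5 latent scale with unit
#' phenotypic variance and discretised afterwards.
#'
#' @return data.frame with columns `trait`, `mean`, `sigma2_g`, `sigma2_e`,
#'   `sex_effect`.
#' @export
default_traits <- function() {
  data.frame(
    trait    = c("liver_fat", "muscle_fat", "body_weight", "liver_score",
                 "hsi", "viscera_score"),
    mean     = c(7.6, 19.2, 3.56, 3.0, 0.8, 3.0),
    sigma2_g = c(2.59, 0.43 * 9.0, 0.58 * 0.83^2, 0.28, 0.19 * 0.01, 0.28),
    sigma2_e = c(4.19, 0.57 * 9.0, 0.42 * 0.83^2, 0.72, 0.81 * 0.01, 0.72),
    sex_effect = c(0.3, 0.5, 0.15, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Default genetic correlation matrix between the simulated traits
#'
#' Liver fat is genetically correlated with muscle fat (0.37), body weight
#' (0.31), liver score (0.70), HSI (0.25) and viscera score (0.28); pairs not
#' involving liver fat default to zero, which keeps the matrix positive
#' semidefinite (the liver-fat correlation vector has norm < 1).
#'
#' @return symmetric 6x6 correlation matrix with unit diagonal.
#' @export
default_genetic_correlations <- function() {
  tr <- default_traits()$trait
  R <- diag(length(tr))
  dimnames(R) <- list(tr, tr)
  rg <- c(muscle_fat = 0.37, body_weight = 0.31, liver_score = 0.70,
          hsi = 0.25, viscera_score = 0.28)
  R["liver_fat", names(rg)] <- rg
  R[names(rg), "liver_fat"] <- rg
  R
}

#' Default fatty-acid panel for the composition simulator
#'
#' Per-fatty-acid mean and SD of relative content (% of total fatty acids) in
#' liver, the sign of the coupling with liver fat (fattier livers carry more
#' 16:1n-7, 18:1n-9 and 18:2n-6 and less 16:0, EPA, DPA and DHA) and the
#' magnitude of the liver-fat correlation used by the generator.
#'
#' @return data.frame with columns `fa`, `mean`, `sd`, `sign`, `cor`.
#' @export
default_fatty_acids <- function() {
  data.frame(
    fa   = c("16:0", "16:1n-7", "18:0", "18:1n-9", "18:2n-6", "18:3n-3",
             "20:5n-3", "22:5n-3", "22:6n-3"),
    mean = c(11.1, 2.3, 5.2, 22.4, 5.6, 2.2, 6.5, 3.5, 13.8),
    sd   = c(1.9, 0.7, 0.6, 5.6, 0.9, 0.4, 0.7, 0.5, 4.0),
    sign = c(-1, 1, 0, 1, 1, 0, -1, -1, -1),
    cor  = c(0.5, 0.6, 0, 0.6, 0.5, 0, 0.5, 0.4, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults describe
#' the study population the package emulates: 634 phenotyped offspring of 39
#' sires x 48 dams, 610 of them genotyped, 48 with liver transcriptomes, 29
#' chromosomes, and trait variance components calibrated to the liver-fat
#' heritability analysis (see \code{\link{default_traits}}).  The SNP panel
#' defaults to 5,000 markers, a scaled stand-in for the ~52,925-SNP array.
#'
#' @param n_individuals number of phenotyped offspring.
#' @param n_genotyped number of offspring carrying genotypes (<= n_individuals).
#' @param n_expression number of offspring with expression data (<= n_genotyped).
#' @param n_sires,n_dams founder counts; each dam is mated to one sire and a
#'   sire x dam pair defines a full-sib family.
#' @param n_chromosomes number of chromosomes SNPs are placed on.
#' @param n_snps number of clean SNPs (QC-violating spikes are added on top).
#' @param maf_range interval in (0, 0.5] for founder second-allele frequencies.
#' @param missing_rate per-entry probability that a clean dosage is missing.
#' @param traits trait panel, see \code{\link{default_traits}}.
#' @param genetic_correlations trait x trait genetic correlation matrix.
#' @param sex_fraction_male proportion of males.
#' @param liver_fat_floor soft lower bound (% fat) applied to liver fat via a
#'   softplus rectification, producing the right-skewed distribution seen in
#'   real livers; set to `NA` for a pure Gaussian trait (used in variance
#'   component recovery studies, where rectification would bias estimates).
#' @param floor_scale softness (in % fat) of the rectification.
#' @param discretize_scores discretise the latent liver/viscera scores onto
#'   the integer 1-5 scale (higher = fattier); `FALSE` keeps them continuous.
#' @param n_genes number of simulated genes.
#' @param assoc_gene_fraction fraction of genes whose expression is coupled to
#'   liver fat.
#' @param assoc_effect_sd SD of the per-gene coupling coefficient (log2 units
#'   per phenotypic SD of liver fat).
#' @param expr_resid_sd residual SD of log2 expression.
#' @param family_variance_expr variance of the full-sib family intercept in
#'   the expression generator (default 10% of the residual variance).
#' @param fatty_acids fatty-acid panel, see \code{\link{default_fatty_acids}}.
#' @param qc_spike named counts `c(call_rate=, maf=, hwe=)` of SNPs injected
#'   with guaranteed QC violations (missingness > 10%, MAF < 0.02, strong
#'   heterozygote excess respectively).
#' @param seed master seed; all stages derive deterministic child seeds.
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 634,
                       n_genotyped = 610,
                       n_expression = 48,
                       n_sires = 39,
                       n_dams = 48,
                       n_chromosomes = 29,
                       n_snps = 5000,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       traits = default_traits(),
                       genetic_correlations = default_genetic_correlations(),
                       sex_fraction_male = 0.55,
                       liver_fat_floor = 4,
                       floor_scale = 0.5,
                       discretize_scores = TRUE,
                       n_genes = 2000,
                       assoc_gene_fraction = 0.1,
                       assoc_effect_sd = 0.8,
                       expr_resid_sd = 0.5,
                       family_variance_expr = 0.1 * 0.5^2,
                       fatty_acids = default_fatty_acids(),
                       qc_spike = c(call_rate = 0, maf = 0, hwe = 0),
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_genotyped = as.integer(n_genotyped),
    n_expression = as.integer(n_expression),
    n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    n_chromosomes = as.integer(n_chromosomes),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    missing_rate = missing_rate,
    traits = traits,
    genetic_correlations = genetic_correlations,
    sex_fraction_male = sex_fraction_male,
    liver_fat_floor = liver_fat_floor,
    floor_scale = floor_scale,
    discretize_scores = isTRUE(discretize_scores),
    n_genes = as.integer(n_genes),
    assoc_gene_fraction = assoc_gene_fraction,
    assoc_effect_sd = assoc_effect_sd,
    expr_resid_sd = expr_resid_sd,
    family_variance_expr = family_variance_expr,
    fatty_acids = fatty_acids,
    qc_spike = qc_spike,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$traits),
            all(c("trait", "mean", "sigma2_g", "sigma2_e", "sex_effect")
                %in% names(cfg$traits)))
  if (cfg$n_sires < 1L || cfg$n_dams < 1L)
    stop("invalid config: need at least one sire and one dam")
  if (cfg$n_sires > cfg$n_individuals)
    stop("invalid config: more sires than individuals")
  if (cfg$n_genotyped > cfg$n_individuals)
    stop("invalid config: n_genotyped exceeds n_individuals")
  if (cfg$n_expression > cfg$n_individuals)
    stop("invalid config: n_expression exceeds n_individuals")
  if (cfg$n_expression > cfg$n_genotyped)
    stop("invalid config: n_expression exceeds n_genotyped")
  if (length(cfg$maf_range) != 2L || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("invalid config: maf_range must be an interval within (0, 0.5]")
  if (any(cfg$traits$sigma2_g < 0) || any(cfg$traits$sigma2_e < 0))
    stop("invalid config: variances must be non-negative")
  R <- cfg$genetic_correlations
  tr <- cfg$traits$trait
  if (!is.matrix(R) || nrow(R) != length(tr) || ncol(R) != length(tr))
    stop("invalid config: genetic_correlations must be a trait x trait matrix")
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10)
    stop("invalid config: correlation matrix must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("invalid config: correlation matrix is not positive semidefinite")
  for (p in c("sex_fraction_male", "assoc_gene_fraction", "missing_rate")) {
    v <- cfg[[p]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("invalid config: %s must lie in [0, 1]", p))
  }
  if (sum(cfg$fatty_acids$mean) >= 100)
    stop("invalid config: fatty-acid means must sum to less than 100%")
  if (any(cfg$qc_spike < 0)) stop("invalid config: qc_spike counts must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  individuals: %d (genotyped %d, expression %d)\n",
              x$n_individuals, x$n_genotyped, x$n_expression))
  cat(sprintf("  founders: %d sires x %d dams; %d chromosomes, %d SNPs\n",
              x$n_sires, x$n_dams, x$n_chromosomes, x$n_snps))
  cat(sprintf("  traits: %s\n", paste(x$traits$trait, collapse = ", ")))
  cat(sprintf("  genes: %d (%.0f%% trait-coupled); seed %d\n",
              x$n_genes, 100 * x$assoc_gene_fraction, x$seed))
  invisible(x)
}
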