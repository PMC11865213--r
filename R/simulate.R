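#' Simulate a two-generation pedigree of full-sib families
#'
#' Mates each dam to a single sire (dams are distributed round-robin over
#' sires, so a sire may serve several dams) and assigns every offspring to a
#' random sire x dam pair.  A full-sib family is one sire x dam pair, so the
#' number of distinct families is at most `n_dams`.  Sex is drawn with the
#' configured male fraction; exactly `n_genotyped` offspring are flagged as
#' genotyped and `n_expression` of those as having expression data.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame (class `pedigree_table`) with columns `individual_id`,
#'   `sire_id`, `dam_id`, `family_id`, `sex`, `genotyped`, `expression`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_individuals
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  dams <- sprintf("D%03d", seq_len(config$n_dams))
  dam_sire <- ((seq_len(config$n_dams) - 1L) %% config$n_sires) + 1L
  fam <- sample.int(config$n_dams, n, replace = TRUE)
  ped <- data.frame(
    individual_id = sprintf("F%04d", seq_len(n)),
    sire_id = sires[dam_sire[fam]],
    dam_id = dams[fam],
    family_id = sprintf("FAM%02d", fam),
    sex = ifelse(runif(n) < config$sex_fraction_male, "male", "female"),
    genotyped = FALSE,
    expression = FALSE,
    stringsAsFactors = FALSE
  )
  ped$genotyped[sample.int(n, config$n_genotyped)] <- TRUE
  geno_idx <- which(ped$genotyped)
  ped$expression[sample(geno_idx, config$n_expression)] <- TRUE
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Simulate SNP genotypes by gene dropping through the pedigree
#'
#' Founder (sire and dam) haplotypes are drawn per SNP in Hardy-Weinberg
#' proportions with a second-allele frequency uniform on `maf_range`;
#' offspring dosages follow by Mendelian transmission of one random allele
#' from each parent, which induces the family co-segregation structure the
#' downstream GRM and GWAS stages rely on.  SNPs are placed in equal-sized
#' blocks on `n_chromosomes` chromosomes with sorted uniform positions.
#' Optionally, `qc_spike` extra SNPs carrying guaranteed quality-control
#' violations are appended: >10% missingness, a minor allele frequency below
#' 0.02, or an all-heterozygote column (extreme Hardy-Weinberg distortion).
#' The violation type of every SNP is recorded in the map (`qc_violation`).
#'
#' @param pedigree a `pedigree_table`.
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_matrix}} covering every pedigree offspring.
#' @export
simulate_genotypes <- function(pedigree, config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 2L))
  n <- nrow(pedigree)
  m <- config$n_snps
  founders <- unique(c(pedigree$sire_id, pedigree$dam_id))
  nf <- length(founders)
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  # founder haplotypes: nf x m matrices of 0/1 alleles (1 = second allele)
  H1 <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  H2 <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  si <- match(pedigree$sire_id, founders)
  di <- match(pedigree$dam_id, founders)
  pick <- function(idx) {       # transmitted allele, one meiosis per entry
    mask <- matrix(runif(n * m) < 0.5, n, m)
    ifelse(mask, H1[idx, , drop = FALSE], H2[idx, , drop = FALSE])
  }
  dos <- pick(si) + pick(di)
  if (config$missing_rate > 0)
    dos[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
  chrom <- rep(seq_len(config$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- integer(m)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(sample.int(5e7, length(idx)))
  }
  map <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(chrom),
    pos = pos,
    allele1 = "A", allele2 = "B",
    qc_violation = "none",
    stringsAsFactors = FALSE
  )
  spikes <- qc_spike_snps(config, n)
  if (!is.null(spikes)) {
    dos <- cbind(dos, spikes$dosage)
    map <- rbind(map, spikes$map)
  }
  dimnames(dos) <- list(pedigree$individual_id, map$snp_id)
  out <- genotype_matrix(dos, map)
  fdos <- H1 + H2
  dimnames(fdos) <- list(founders, map$snp_id[seq_len(m)])
  attr(out, "founder_dosage") <- fdos      # truth for Mendelian checks
  out
}

# construct SNP columns guaranteed to violate one QC filter each
qc_spike_snps <- function(config, n) {
  counts <- config$qc_spike
  total <- sum(counts)
  if (total == 0) return(NULL)
  cols <- list(); types <- character(0)
  p_mid <- mean(config$maf_range)
  for (k in seq_len(counts[["call_rate"]] %||% 0)) {
    v <- rbinom(n, 2L, p_mid)
    v[sample.int(n, ceiling(0.15 * n))] <- NA_integer_   # call rate 0.85
    cols[[length(cols) + 1L]] <- v; types <- c(types, "call_rate")
  }
  for (k in seq_len(counts[["maf"]] %||% 0)) {
    v <- integer(n); v[sample.int(n, 1L)] <- 1L           # MAF = 1/(2n)
    cols[[length(cols) + 1L]] <- v; types <- c(types, "maf")
  }
  for (k in seq_len(counts[["hwe"]] %||% 0)) {
    cols[[length(cols) + 1L]] <- rep(1L, n)               # all heterozygote
    types <- c(types, "hwe")
  }
  dosage <- do.call(cbind, cols)
  map <- data.frame(
    snp_id = sprintf("qcfail%03d", seq_along(types)),
    chrom = as.character(sample.int(config$n_chromosomes, length(types),
                                    replace = TRUE)),
    pos = sample.int(5e7, length(types)),
    allele1 = "A", allele2 = "B",
    qc_violation = types,
    stringsAsFactors = FALSE
  )
  list(dosage = dosage, map = map)
}

#' Simulate multi-trait polygenic phenotypes
#'
#' Additive genetic values are built from per-SNP effects: a raw score matrix
#' `Z B` (centred dosages times i.i.d. normal effect rows — the infinitesimal
#' architecture assumed by GREML) is recoloured so that the realised genetic
#' covariance across the simulated population equals exactly
#' `diag(sd_g) R diag(sd_g)` with `R` the configured genetic correlation
#' matrix.  Residuals are multivariate normal with the configured residual
#' variances (independent across traits), and a centred fixed sex effect is
#' added.  Liver fat is passed through a softplus rectification with a soft
#' floor at `liver_fat_floor` (default 4% fat), giving the right-skewed
#' distribution observed in real livers; disable with `liver_fat_floor = NA`.
#' Liver and viscera scores are latent traits on a 1-5 scale, discretised by
#' rounding (higher = fattier, i.e. already on the reversed presentation
#' scale).  HSI is realised by converting the latent HSI trait into a liver
#' weight given the simulated body weight, then recomputing liver weight /
#' body weight x 100.
#'
#' @param genotypes `genotype_matrix` covering all pedigree individuals.
#' @param pedigree `pedigree_table`.
#' @param config \code{\link{sim_config}}.
#' @return data.frame (class `phenotype_table`) with one row per individual
#'   and one column per trait plus `body_weight_g`, `liver_weight_g`.  The
#'   matrix of true additive genetic values is attached as attribute
#'   `"genetic_values"`.
#' @export
simulate_phenotypes <- function(genotypes, pedigree, config) {
  validate_sim_config(config)
  if (!all(pedigree$individual_id %in% rownames(genotypes$dosage)))
    stop("genotypes do not cover all pedigree individuals")
  set.seed(child_seed(config$seed, 3L))
  traits <- config$traits
  tnames <- traits$trait
  R <- config$genetic_correlations
  n <- nrow(pedigree)
  clean <- genotypes$map$qc_violation == "none"
  S <- genotypes$dosage[pedigree$individual_id, clean, drop = FALSE]
  pbar <- colMeans(S, na.rm = TRUE) / 2
  Z <- sweep(S, 2L, 2 * pbar)
  Z[is.na(Z)] <- 0
  u <- genetic_values_exact(Z, traits$sigma2_g, R)
  colnames(u) <- tnames
  E <- sapply(traits$sigma2_e, function(v) rnorm(n, 0, sqrt(v)))
  sexc <- ifelse(pedigree$sex == "male", 0.5, -0.5)
  Y <- sweep(u + E, 2L, traits$mean, "+") + outer(sexc, traits$sex_effect)
  colnames(Y) <- tnames
  ph <- data.frame(pedigree[, c("individual_id", "sire_id", "dam_id",
                                "family_id", "sex", "genotyped", "expression")],
                   Y, stringsAsFactors = FALSE)
  if (!is.null(config$liver_fat_floor) && is.finite(config$liver_fat_floor)) {
    s <- config$floor_scale
    x <- ph$liver_fat - config$liver_fat_floor
    ph$liver_fat <- config$liver_fat_floor + s * log1p(exp(x / s))
  }
  if (config$discretize_scores) {
    ph$liver_score <- pmin(5L, pmax(1L, as.integer(round(ph$liver_score))))
    ph$viscera_score <- pmin(5L, pmax(1L, as.integer(round(ph$viscera_score))))
  }
  ph$body_weight <- pmax(ph$body_weight, 0.2)   # slaughter fish weigh > 0
  ph$body_weight_g <- 1000 * ph$body_weight
  hsi_latent <- pmax(ph$hsi, 0.3)
  ph$liver_weight_g <- hsi_latent * ph$body_weight_g / 100
  ph$hsi <- hepatosomatic_index(ph$liver_weight_g, ph$body_weight_g)
  attr(ph, "genetic_values") <- u
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

# raw polygenic scores Z B recoloured to an exact target genetic covariance;
# traits with zero genetic variance get u = 0
genetic_values_exact <- function(Z, sigma2_g, R) {
  n <- nrow(Z)
  Tn <- length(sigma2_g)
  u <- matrix(0, n, Tn)
  pos <- which(sigma2_g > 0)
  if (!length(pos)) return(u)
  B <- matrix(rnorm(ncol(Z) * length(pos)), ncol(Z), length(pos))
  Graw <- Z %*% B
  Graw <- scale(Graw, center = TRUE, scale = FALSE)
  Cemp <- crossprod(Graw) / (n - 1)
  Ctar <- diag(sqrt(sigma2_g[pos]), length(pos)) %*%
    R[pos, pos, drop = FALSE] %*% diag(sqrt(sigma2_g[pos]), length(pos))
  W <- backsolve(chol(Cemp), diag(length(pos)))   # whitening
  u[, pos] <- Graw %*% W %*% chol(Ctar)
  u
}

#' Simulate a trait-coupled gene expression matrix
#'
#' For the expression-flagged individuals, per-gene log2 expression is drawn
#' as a gene baseline plus, for a configured fraction of genes, a linear
#' coupling to standardised liver fat with coefficient drawn from
#' `N(0, assoc_effect_sd^2)`, plus a small fixed sex effect, a full-sib
#' family random intercept and Gaussian noise.  Fragment counts are then
#' Poisson with rate FPKM x length/1e3 x library/1e6, so FPKM can be
#' recovered by the normalisation stage.  The set of coupled genes is a
#' deterministic function of the configuration seed and is shared with
#' \code{\link{simulate_annotation_and_terms}}.
#'
#' @param phenotypes `phenotype_table` (liver fat and family labels used).
#' @param config \code{\link{sim_config}}.
#' @return list (class `expression_sim`) with `counts` (gene x sample integer
#'   matrix), `lengths` (bp per gene), and `truth` (data.frame `gene_id`,
#'   `associated`, `coef`).
#' @export
simulate_expression <- function(phenotypes, config) {
  validate_sim_config(config)
  samp <- phenotypes[phenotypes$expression, , drop = FALSE]
  if (!nrow(samp)) stop("no expression-flagged individuals")
  truth <- expression_truth(config)
  set.seed(child_seed(config$seed, 4L))
  ng <- config$n_genes; ns <- nrow(samp)
  mu <- rnorm(ng, 4, 1.5)
  len <- as.integer(round(runif(ng, 500, 5000)))
  sex_eff <- rnorm(ng, 0, 0.2)
  fams <- unique(samp$family_id)
  fam_eff <- matrix(rnorm(ng * length(fams), 0,
                          sqrt(config$family_variance_expr)), ng, length(fams))
  zfat <- as.numeric(scale(samp$liver_fat))
  male <- as.numeric(samp$sex == "male")
  L <- mu + outer(truth$coef, zfat) + outer(sex_eff, male) +
    fam_eff[, match(samp$family_id, fams), drop = FALSE] +
    matrix(rnorm(ng * ns, 0, config$expr_resid_sd), ng, ns)
  fpkm <- pmax(2^L - 1, 0)
  lib <- runif(ns, 4e6, 6e6)
  lam <- fpkm * (len / 1e3) * rep(lib / 1e6, each = ng)
  counts <- matrix(rpois(ng * ns, lam), ng, ns,
                   dimnames = list(truth$gene_id, samp$individual_id))
  structure(list(counts = counts,
                 lengths = setNames(len, truth$gene_id),
                 truth = truth),
            class = "expression_sim")
}

# which genes are trait-coupled, and with what coefficient; deterministic in
# the config seed so annotation/term construction can reuse it
expression_truth <- function(config) {
  set.seed(child_seed(config$seed, 7L))
  ng <- config$n_genes
  n_assoc <- round(config$assoc_gene_fraction * ng)
  idx <- sort(sample.int(ng, n_assoc))
  coef <- numeric(ng)
  coef[idx] <- rnorm(n_assoc, 0, config$assoc_effect_sd)
  data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
             associated = seq_len(ng) %in% idx,
             coef = coef, stringsAsFactors = FALSE)
}

#' Simulate a compositional liver fatty-acid panel
#'
#' For the expression-flagged individuals, each fatty acid's relative content
#' (% of total fatty acids) is drawn around its configured mean with the
#' configured coupling to standardised liver fat: value = mean + sign x |r| x
#' SD x z(liver fat) + noise with SD x sqrt(1 - r^2), truncated at zero.  The
#' remaining share of the profile is closed to exactly 100% through an
#' "other" pool.
#'
#' @param phenotypes `phenotype_table`.
#' @param config \code{\link{sim_config}}.
#' @return data.frame (class `fatty_acid_table`): `individual_id`, one column
#'   per fatty acid, and `other`; rows sum to 100 exactly.
#' @export
simulate_fatty_acids <- function(phenotypes, config) {
  validate_sim_config(config)
  if (!"liver_fat" %in% names(phenotypes))
    stop("phenotypes must contain liver_fat")
  samp <- phenotypes[phenotypes$expression, , drop = FALSE]
  set.seed(child_seed(config$seed, 5L))
  fa <- config$fatty_acids
  z <- as.numeric(scale(samp$liver_fat))
  n <- nrow(samp)
  vals <- sapply(seq_len(nrow(fa)), function(i) {
    r <- fa$sign[i] * abs(fa$cor[i])
    fa$mean[i] + r * fa$sd[i] * z + rnorm(n, 0, fa$sd[i] * sqrt(1 - r^2))
  })
  vals <- pmax(vals, 0)
  tot <- rowSums(vals)
  over <- tot > 99.5                       # keep a positive "other" pool
  if (any(over)) {
    vals[over, ] <- vals[over, , drop = FALSE] * (99.5 / tot[over])
    tot[over] <- 99.5
  }
  out <- data.frame(individual_id = samp$individual_id, vals, other = 100 - tot,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2:(1 + nrow(fa))] <- fa$fa
  class(out) <- c("fatty_acid_table", "data.frame")
  out
}

#' Simulate gene annotation and gene-to-term maps
#'
#' Places non-overlapping gene intervals (1-based, inclusive) round-robin on
#' the configured chromosomes and assigns genes to functional terms.  Most
#' terms are random draws from all genes; a few constructed terms are filled
#' predominantly with trait-coupled genes (per \code{\link{simulate_expression}}'s
#' truth labels), so the enrichment stage has known positives.
#'
#' @param config \code{\link{sim_config}}.
#' @param n_terms number of random terms (three enriched terms are added).
#' @return list with `annotation` (data.frame `gene_id`, `gene_name`,
#'   `chrom`, `start`, `end`, class `annotation_index`) and `terms`
#'   (data.frame `gene_id`, `term_id`).
#' @export
simulate_annotation_and_terms <- function(config, n_terms = 40) {
  validate_sim_config(config)
  truth <- expression_truth(config)
  set.seed(child_seed(config$seed, 6L))
  ng <- config$n_genes
  chrom <- rep(seq_len(config$n_chromosomes), length.out = ng)
  chrom <- sort(chrom)
  start <- integer(ng); end <- integer(ng)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    glen <- as.integer(round(runif(length(idx), 5000, 30000)))
    gap <- as.integer(round(runif(length(idx), 10000, 50000)))
    st <- 1L + cumsum(gap) + c(0L, cumsum(glen[-length(glen)]))
    start[idx] <- st
    end[idx] <- st + glen - 1L
  }
  ann <- data.frame(gene_id = truth$gene_id,
                    gene_name = toupper(truth$gene_id),
                    chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  class(ann) <- c("annotation_index", "data.frame")
  assoc <- truth$gene_id[truth$associated]
  maps <- list()
  for (t in seq_len(n_terms)) {
    size <- sample(5:100, 1L)
    maps[[t]] <- data.frame(gene_id = sample(truth$gene_id, size),
                            term_id = sprintf("TERM%03d", t),
                            stringsAsFactors = FALSE)
  }
  for (t in 1:3) {                       # enriched-by-construction terms
    k <- min(length(assoc), 20L)
    maps[[n_terms + t]] <- data.frame(
      gene_id = sample(assoc, k),
      term_id = sprintf("TERM_ENRICHED%d", t),
      stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, maps)
  terms <- terms[!duplicated(terms), ]
  rownames(terms) <- NULL
  list(annotation = ann, terms = terms)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running every generator stage in order.
#'
#' @param config \code{\link{sim_config}}.
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `expression`,
#'   `fatty_acids`, `annotation`, `terms`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(geno, ped, config)
  expr <- simulate_expression(ph, config)
  fa <- simulate_fatty_acids(ph, config)
  at <- simulate_annotation_and_terms(config)
  list(pedigree = ped, genotypes = geno, phenotypes = ph, expression = expr,
       fatty_acids = fa, annotation = at$annotation, terms = at$terms)
}
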