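# Small shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# ~120 fish, 600 SNPs on 6 chromosomes: big enough for GRM/GWAS mechanics,
# small enough to be instant
small_config <- function(seed = 101, n_genes = 200, n_expression = 24, ...) {
  sim_config(n_individuals = 120, n_genotyped = 110,
             n_expression = n_expression, n_sires = 8, n_dams = 12,
             n_chromosomes = 6, n_snps = 600, n_genes = n_genes,
             liver_fat_floor = NA, seed = seed, ...)
}

small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- small_config()
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(geno, ped, cfg)
    .fixtures$small <- list(cfg = cfg, ped = ped, geno = geno, ph = ph)
  }
  .fixtures$small
}

# genotype matrix from explicit dosages (SNPs in columns)
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  dimnames(dosage) <- list(sprintf("ind%02d", seq_len(n)),
                           sprintf("s%03d", seq_len(m)))
  genotype_matrix(dosage, data.frame(
    snp_id = colnames(dosage),
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE))
}
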