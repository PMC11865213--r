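test_that("pedigree has the configured family structure and flags", {
  cfg <- sim_config(seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 634L)
  expect_equal(sum(ped$genotyped), 610L)
  expect_equal(sum(ped$expression), 48L)
  expect_lte(length(unique(ped$family_id)), 48L)
  expect_true(all(ped$expression <= ped$genotyped))  # expression subset of genotyped
  # family constant within a sire x dam pair
  pair <- paste(ped$sire_id, ped$dam_id)
  expect_equal(length(unique(pair)), length(unique(ped$family_id)))
  # founders disjoint from offspring ids
  expect_length(intersect(ped$individual_id, c(ped$sire_id, ped$dam_id)), 0)
})

test_that("single-cross pedigree puts all offspring in one family", {
  cfg <- sim_config(n_individuals = 20, n_genotyped = 20, n_expression = 2,
                    n_sires = 1, n_dams = 1, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(length(unique(ped$family_id)), 1L)
})

test_that("generator stages are deterministic under a fixed seed", {
  cfg <- small_config(seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$fatty_acids, b$fatty_acids)
  expect_identical(a$annotation, b$annotation)
})

test_that("gene dropping is Mendelian-consistent with parental genotypes", {
  sm <- small_sim()
  clean <- sm$geno$map$qc_violation == "none"
  dos <- sm$geno$dosage[, clean, drop = FALSE]
  fdos <- attr(sm$geno, "founder_dosage")
  sire <- fdos[sm$ped$sire_id, , drop = FALSE]
  dam <- fdos[sm$ped$dam_id, , drop = FALSE]
  ok <- is.na(dos) |
    (dos <= 2 - (sire == 0) - (dam == 0)) &   # a 0-parent cannot transmit B
    (dos >= (sire == 2) + (dam == 2))         # a 2-parent must transmit B
  expect_true(all(ok))
  # both parents homozygous reference => every offspring dosage is 0
  fixed0 <- sire == 0 & dam == 0
  expect_true(all(dos[fixed0] == 0, na.rm = TRUE))
})

test_that("offspring allele frequency tracks the founder frequency", {
  cfg <- sim_config(n_individuals = 2000, n_genotyped = 2000, n_expression = 2,
                    n_sires = 200, n_dams = 300, n_snps = 300,
                    n_chromosomes = 5, maf_range = c(0.3, 0.3),
                    missing_rate = 0, seed = 12)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  freq <- colMeans(geno$dosage) / 2
  # binomial sampling oracle: SE of a founder-derived frequency at p = 0.3;
  # transmission adds noise, so allow 4 SEs around the target on the mean
  se <- sqrt(0.3 * 0.7 / (2 * 500))
  expect_lt(abs(mean(freq) - 0.3), 4 * se)
  expect_gt(min(freq), 0.1)
  expect_lt(max(freq), 0.5)
})

test_that("QC spike SNPs are constructed to fail their filter", {
  cfg <- small_config(seed = 9, qc_spike = c(call_rate = 15, maf = 15, hwe = 15))
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_equal(ncol(geno$dosage), 600L + 45L)
  qc <- apply_qc(geno)
  removed <- geno$map$snp_id[!geno$map$snp_id %in% qc$genotypes$map$snp_id]
  spikes <- geno$map$snp_id[geno$map$qc_violation != "none"]
  expect_true(all(spikes %in% removed))
  expect_gte(sum(!snp_metrics(geno)$pass), 45)
})

test_that("realized genetic variance and correlation match the configuration", {
  sm <- small_sim()
  u <- attr(sm$ph, "genetic_values")
  tr <- sm$cfg$traits
  for (j in seq_len(nrow(tr)))
    expect_equal(var(u[, tr$trait[j]]), tr$sigma2_g[j], tolerance = 1e-8)
  R <- sm$cfg$genetic_correlations
  expect_equal(cor(u[, "liver_fat"], u[, "liver_score"]),
               R["liver_fat", "liver_score"], tolerance = 1e-8)
})

test_that("realized genetic variance stays near target across seeds", {
  vars <- sapply(1:20, function(k) {
    cfg <- sim_config(n_individuals = 80, n_genotyped = 80, n_expression = 5,
                      n_sires = 6, n_dams = 8, n_snps = 300, n_chromosomes = 4,
                      seed = 400 + k)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(geno, ped, cfg)
    var(attr(ph, "genetic_values")[, "liver_fat"])
  })
  expect_true(all(abs(vars - 2.59) / 2.59 < 0.10))
})

test_that("zero genetic variance yields zero genetic values", {
  tr <- default_traits()
  tr$sigma2_g[tr$trait == "liver_fat"] <- 0
  cfg <- small_config(seed = 31)
  cfg$traits <- tr
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  u <- attr(ph, "genetic_values")
  expect_equal(unname(u[, "liver_fat"]), rep(0, nrow(ph)))
  expect_gt(var(u[, "muscle_fat"]), 0)
})

test_that("liver fat is floored near 4% with a right tail", {
  cfg <- sim_config(seed = 3)      # defaults: floor active
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  expect_gte(min(ph$liver_fat), 4)
  expect_lt(min(ph$liver_fat), 5)
  m <- mean(ph$liver_fat)
  expect_gt(mean((ph$liver_fat - m)^3) / sd(ph$liver_fat)^3, 0)  # right skew
  expect_true(all(ph$liver_score %in% 1:5))
  expect_true(all(ph$hsi > 0))
})

test_that("expression generator couples configured genes to liver fat", {
  sm <- small_sim()
  expr <- simulate_expression(sm$ph, sm$cfg)
  expect_equal(dim(expr$counts), c(200L, 24L))
  expect_equal(sum(expr$truth$associated), round(0.1 * 200))
  expect_true(all(expr$counts >= 0))
  expect_true(all(expr$truth$coef[!expr$truth$associated] == 0))
  # strongest coupled gene should correlate with liver fat in sign
  g <- which.max(abs(expr$truth$coef))
  l2 <- log2(expr$counts[g, ] + 1)
  fat <- sm$ph$liver_fat[match(colnames(expr$counts), sm$ph$individual_id)]
  expect_equal(sign(cor(l2, fat)), sign(expr$truth$coef[g]))
})

test_that("null expression generator gives uniform downstream p-values", {
  # 48 expression samples as in the emulated study; exact t reference so the
  # per-gene test is calibrated at this sample size
  cfg <- small_config(seed = 55, assoc_effect_sd = 0, n_genes = 2000,
                      n_expression = 48)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  expr <- simulate_expression(ph, cfg)
  em <- normalize_expression(expr$counts, expr$lengths)
  scan <- run_association_scan(em, ph, reference = "t")
  p <- scan$p_value[!is.na(scan$p_value)]
  expect_gt(length(p), 1500)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fatty-acid rows close to 100 with calibrated means and signs", {
  cfg <- sim_config(seed = 21)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  fa <- simulate_fatty_acids(ph, cfg)
  expect_equal(nrow(fa), 48L)
  sums <- rowSums(fa[, -1])
  expect_equal(sums, rep(100, 48), tolerance = 1e-9)
  expect_true(all(fa[, -1] >= 0))
  expect_lt(abs(mean(fa[["18:1n-9"]]) - 22.4), 2.0)
  fat <- ph$liver_fat[match(fa$individual_id, ph$individual_id)]
  expect_gt(spearman_correlation(fa[["18:1n-9"]], fat)$rho, 0)
  expect_lt(spearman_correlation(fa[["22:6n-3"]], fat)$rho, 0)
})

test_that("decoupled fatty-acid generator loses the liver-fat correlations", {
  fa_cfgdf <- default_fatty_acids()
  fa_cfgdf$sign <- 0
  cfg <- sim_config(seed = 22, fatty_acids = fa_cfgdf)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  fa <- simulate_fatty_acids(ph, cfg)
  fat <- ph$liver_fat[match(fa$individual_id, ph$individual_id)]
  rhos <- sapply(fa_cfgdf$fa, function(f) spearman_correlation(fa[[f]], fat)$rho)
  expect_lt(max(abs(rhos)), 0.45)   # only sampling noise at n = 48
})

test_that("annotation covers all chromosomes without overlap and round-trips", {
  sm <- small_sim()
  at <- simulate_annotation_and_terms(sm$cfg)
  ann <- at$annotation
  expect_setequal(unique(ann$chrom), as.character(1:6))
  expect_true(all(ann$end >= ann$start))
  for (cc in unique(ann$chrom)) {
    a <- ann[ann$chrom == cc, ]
    a <- a[order(a$start), ]
    expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, path)
  back <- read_annotation_gff3(path)
  back <- back[match(ann$gene_id, back$gene_id), ]
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$chrom, ann$chrom)
})

test_that("constructed enriched terms are flagged by the enrichment stage", {
  sm <- small_sim()
  at <- simulate_annotation_and_terms(sm$cfg)
  truth <- simulate_expression(sm$ph, sm$cfg)$truth
  res <- enrich_terms(truth$gene_id[truth$associated], truth$gene_id, at$terms)
  enr <- res[grepl("ENRICHED", res$term_id), ]
  expect_true(all(enr$enriched))
})
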