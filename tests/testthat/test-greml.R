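test_that("heritability and CV worked examples evaluate exactly", {
  expect_equal(round(heritability_from_components(2.59, 4.19), 2), 0.38)
  expect_equal(heritability_from_components(0, 5), 0)
  expect_equal(heritability_from_components(5, 0), 1)
  expect_error(heritability_from_components(0, 0), "undefined")
  expect_error(heritability_from_components(-1, 2), ">= 0")
  expect_equal(round(coefficient_of_variation(2.60, 7.6), 3), 0.342)
  expect_equal(round(coefficient_of_variation(1.61, 7.6), 3), 0.212)
  expect_equal(coefficient_of_variation(0, 3), 0)
  expect_error(coefficient_of_variation(1, 0), "positive")
})

test_that("REML optimum dominates a 50x50 likelihood grid", {
  cfg <- sim_config(n_individuals = 30, n_genotyped = 30, n_expression = 3,
                    n_sires = 4, n_dams = 5, n_snps = 150, n_chromosomes = 3,
                    missing_rate = 0, liver_fat_floor = NA, seed = 71)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  grm <- compute_grm(apply_qc(geno)$genotypes)
  des <- model_design(ph, "liver_fat", "sex", sample_ids = grm$sample_ids)
  fit <- suppressWarnings(fit_greml_univariate(des, grm))
  G <- grm$values
  y <- des$Y[, 1]
  vp <- var(y)
  grid <- seq(0.02, 2, length.out = 50) * vp
  ll_grid <- outer(grid, grid, Vectorize(function(sg, se)
    reml_loglik(y, des$X, G, sg, se)))
  expect_gte(fit$reml_loglik, max(ll_grid) - 1e-6)
})

test_that("variance-component estimates are scale- and shift-equivariant", {
  sm <- small_sim()
  grm <- compute_grm(apply_qc(sm$geno)$genotypes)
  des <- model_design(sm$ph, "liver_fat", "sex", sample_ids = grm$sample_ids)
  fit <- fit_greml_univariate(des, grm)
  des_shift <- des; des_shift$Y <- des$Y + 100
  fit_shift <- fit_greml_univariate(des_shift, grm)
  expect_equal(fit_shift$sigma2_g, fit$sigma2_g, tolerance = 1e-5)
  expect_equal(fit_shift$h2, fit$h2, tolerance = 1e-6)
  des_scale <- des; des_scale$Y <- des$Y * 3
  fit_scale <- fit_greml_univariate(des_scale, grm)
  expect_equal(fit_scale$sigma2_g, 9 * fit$sigma2_g, tolerance = 1e-4)
  expect_equal(fit_scale$sigma2_e, 9 * fit$sigma2_e, tolerance = 1e-4)
  expect_equal(fit_scale$h2, fit$h2, tolerance = 1e-6)
})

test_that("null heritability lands on the lower boundary and is flagged", {
  tr <- default_traits()
  tr$sigma2_g[tr$trait == "liver_fat"] <- 0
  h2s <- sapply(1:5, function(k) {
    cfg <- small_config(seed = 500 + k)
    cfg$traits <- tr
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(geno, ped, cfg)
    grm <- compute_grm(apply_qc(geno)$genotypes)
    des <- model_design(ph, "liver_fat", "sex", sample_ids = grm$sample_ids)
    fit_greml_univariate(des, grm)$h2
  })
  expect_lt(mean(h2s), 0.1)
  expect_lt(median(h2s), 0.05)
})

test_that("accepted AI steps never decrease the restricted log-likelihood", {
  # monotonicity is enforced by step-halving; verify the final loglik beats
  # the starting 50/50 split on several replicates
  for (k in 1:3) {
    cfg <- small_config(seed = 600 + k)
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(geno, ped, cfg)
    grm <- compute_grm(apply_qc(geno)$genotypes)
    des <- model_design(ph, "liver_fat", "sex", sample_ids = grm$sample_ids)
    fit <- fit_greml_univariate(des, grm)
    vp <- var(des$Y[, 1])
    ll0 <- reml_loglik(des$Y[, 1], des$X,
                       grm$values[match(des$sample_ids, grm$sample_ids),
                                  match(des$sample_ids, grm$sample_ids)],
                       vp / 2, vp / 2)
    expect_gte(fit$reml_loglik, ll0 - 1e-8)
    expect_true(fit$converged)
  }
})

test_that("log-transform option refits on the log scale", {
  sm <- small_sim()
  grm <- compute_grm(apply_qc(sm$geno)$genotypes)
  des <- model_design(sm$ph, "liver_fat", "sex", sample_ids = grm$sample_ids)
  fit_log <- fit_greml_univariate(des, grm, log_transform = TRUE)
  expect_true(is.finite(fit_log$h2))
  # components now on the log scale: total variance near var(log y)
  expect_equal(fit_log$sigma2_g + fit_log$sigma2_e, var(log(des$Y[, 1])),
               tolerance = 0.2)
})

test_that("duplicated trait gives a boundary genetic correlation of 1", {
  sm <- small_sim()
  grm <- compute_grm(apply_qc(sm$geno)$genotypes)
  des <- model_design(sm$ph, c("liver_fat", "liver_fat"), "sex",
                      sample_ids = grm$sample_ids)
  colnames(des$Y) <- c("t1", "t2")
  fit <- fit_greml_bivariate(des, grm)
  expect_gte(fit$rg, 0.99)
})

test_that("independent traits give near-zero genetic correlation", {
  rgs <- sapply(1:6, function(k) {
    cfg <- small_config(seed = 700 + k, discretize_scores = FALSE)
    R <- default_genetic_correlations()
    R[] <- diag(nrow(R))                 # fully independent genetics
    cfg$genetic_correlations <- R
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    ph <- simulate_phenotypes(geno, ped, cfg)
    grm <- compute_grm(apply_qc(geno)$genotypes)
    des <- model_design(ph, c("liver_fat", "muscle_fat"), "sex",
                        sample_ids = grm$sample_ids)
    fit_greml_bivariate(des, grm)$rg
  })
  expect_lt(abs(mean(rgs)), 0.25)        # n = 120: noisy but centred at 0
})

test_that("bivariate likelihood factorises at independence; marginals agree", {
  cfg <- small_config(seed = 88, discretize_scores = FALSE)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  set.seed(1)
  ph$noise <- rnorm(nrow(ph))            # second trait: independent noise
  grm <- compute_grm(apply_qc(geno)$genotypes)
  des1 <- model_design(ph, "liver_fat", "sex", sample_ids = grm$sample_ids)
  des2 <- model_design(ph, "noise", "sex", sample_ids = grm$sample_ids)
  uni1 <- fit_greml_univariate(des1, grm)
  uni2 <- fit_greml_univariate(des2, grm)
  # exact identity: with zero genetic and residual cross-covariances the
  # bivariate restricted likelihood is the sum of the univariate ones
  idx <- match(des1$sample_ids, grm$sample_ids)
  G <- grm$values[idx, idx]
  ee <- eigen(G, symmetric = TRUE)
  st <- salmofat:::biv_eigen_state(
    c(uni1$sigma2_g, 0, uni2$sigma2_g, uni1$sigma2_e, 0, uni2$sigma2_e),
    as.numeric(crossprod(ee$vectors, des1$Y[, 1])),
    as.numeric(crossprod(ee$vectors, des2$Y[, 1])),
    crossprod(ee$vectors, des1$X), pmax(ee$values, 0))
  expect_equal(st$loglik, uni1$reml_loglik + uni2$reml_loglik,
               tolerance = 1e-8)
  # the free joint fit shifts the marginal only through the (small) sampled
  # cross-covariance, so the marginal heritability agrees closely
  biv <- fit_greml_bivariate(
    model_design(ph, c("liver_fat", "noise"), "sex",
                 sample_ids = grm$sample_ids), grm)
  expect_lt(abs(biv$h2[1] - uni1$h2), 0.01)
})

test_that("dense and eigen-factorised bivariate paths agree", {
  cfg <- small_config(seed = 91, discretize_scores = FALSE)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  grm <- compute_grm(apply_qc(geno)$genotypes)
  des <- model_design(ph, c("liver_fat", "liver_score"), "sex",
                      sample_ids = grm$sample_ids)
  fit_eigen <- fit_greml_bivariate(des, grm)
  # the dense path triggers on missing data; one missing record changes the
  # fit only marginally, so drop none and call the dense engine directly
  fit_dense <- salmofat:::biv_reml_dense(des$Y, des$X,
    grm$values[match(des$sample_ids, grm$sample_ids),
               match(des$sample_ids, grm$sample_ids)], 100L, 1e-8)
  expect_equal(fit_dense$rg, fit_eigen$rg, tolerance = 1e-4)
  expect_equal(fit_dense$reml_loglik, fit_eigen$reml_loglik, tolerance = 1e-5)
  # and with genuinely missing records the dense path still converges
  des$Y[1:5, 2] <- NA
  fit_miss <- fit_greml_bivariate(des, grm)
  expect_true(fit_miss$converged)
  expect_lt(abs(fit_miss$rg - fit_eigen$rg), 0.2)
})

test_that("degenerate bivariate inputs error clearly", {
  sm <- small_sim()
  grm <- compute_grm(apply_qc(sm$geno)$genotypes)
  des <- model_design(sm$ph, c("liver_fat", "muscle_fat"), "sex",
                      sample_ids = grm$sample_ids)
  des$Y[, 2] <- 1
  expect_error(fit_greml_bivariate(des, grm), "degenerate")
})
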