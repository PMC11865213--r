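#' Bonferroni significance thresholds
#'
#' Genome-wide cutoff `alpha / n_snps_total` and chromosome-wide cutoff
#' `alpha / avg_snps_per_chr`, with their -log10 equivalents.
#'
#' @param n_snps_total total number of SNPs tested genome-wide.
#' @param avg_snps_per_chr average number of SNPs per chromosome.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `genome_wide_p`, `chrom_wide_p`, `genome_wide_log10`,
#'   `chrom_wide_log10`.
#' @export
bonferroni_thresholds <- function(n_snps_total, avg_snps_per_chr,
                                  alpha = 0.05) {
  if (n_snps_total < 1 || avg_snps_per_chr < 1)
    stop("test counts must be >= 1")
  gw <- alpha / n_snps_total
  cw <- alpha / avg_snps_per_chr
  list(genome_wide_p = gw, chrom_wide_p = cw,
       genome_wide_log10 = -log10(gw), chrom_wide_log10 = -log10(cw))
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / 0.455`, the observed median 1-df association
#' chi-square divided by its null median; values near 1 indicate calibrated
#' tests.
#'
#' @param chi2 vector of 1-df chi-square statistics; alternatively supply
#'   `p` and the statistics are recovered via the inverse survival function.
#' @param p optional vector of p-values (used when `chi2` is missing).
#' @return scalar lambda.
#' @export
inflation_factor <- function(chi2 = NULL, p = NULL) {
  if (is.null(chi2)) {
    if (is.null(p)) stop("supply chi2 statistics or p-values")
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[is.finite(chi2)]
  if (!length(chi2)) stop("empty chi-square vector")
  median(chi2) / 0.455
}

#' Mixed-linear-model association with leave-one-chromosome-out GRMs
#'
#' Fits, for each SNP, `y = X b + s alpha + u + e` where `u` has covariance
#' `G(-c) sigma2_g` built from all SNPs off the SNP's own chromosome
#' (avoiding proximal contamination), with genotypes coded 0/1/2 as the count
#' of the second allele (missing dosages mean-imputed).  Variance components
#' are estimated once genome-wide with the full GRM and reused for every
#' leave-one-chromosome-out analysis (re-estimation per chromosome via
#' `per_chrom_vc = TRUE`).  Fixed covariates default to sex plus the first
#' two principal components of the full GRM.  The allele-substitution effect
#' and its SE come from generalised least squares under
#' `V(-c) = G(-c) sigma2_g + I sigma2_e`; p-values are 1-df Wald chi-square.
#' SNPs without a chromosome assignment (label `NA`, `"0"`, `"Un"` or
#' `"unknown"`) are tested against the full-genome GRM and reported in a
#' separate stratum (`loco = FALSE`).
#'
#' @param genotypes post-QC `genotype_matrix`.
#' @param phenotypes data.frame with `individual_id`, the trait and
#'   covariates; only samples present in `genotypes` are used.
#' @param trait trait column name (default `"liver_fat"`).
#' @param covariates covariate columns (default `"sex"`).
#' @param n_pcs number of GRM principal components added as covariates.
#' @param per_chrom_vc re-estimate variance components per LOCO chromosome.
#' @param alpha family-wise error rate for the Bonferroni thresholds.
#' @return object of class `gwas_result`: `snps` (data.frame with `snp_id`,
#'   `chrom`, `pos`, `freq`, `alpha`, `se`, `chi2`, `p`, `loco`), `lambda`,
#'   `thresholds`, `vc` (genome-wide variance components), `n`.
#' @export
mlma_loco <- function(genotypes, phenotypes, trait = "liver_fat",
                      covariates = "sex", n_pcs = 2, per_chrom_vc = FALSE,
                      alpha = 0.05) {
  ids <- intersect(rownames(genotypes$dosage), phenotypes$individual_id)
  ids <- ids[!is.na(phenotypes[[trait]][match(ids, phenotypes$individual_id)])]
  if (length(ids) < 3) stop("too few samples with genotypes and phenotypes")
  geno <- subset_samples(genotypes, ids)
  grm_full <- compute_grm(geno)
  extra <- if (n_pcs > 0) grm_pca(grm_full, n_pcs) else NULL
  design <- model_design(phenotypes, trait, covariates, extra = extra,
                         sample_ids = ids)
  if (ncol(design$X) + 2 > length(ids))
    stop("too few samples for the fixed-effect design")
  vc <- fit_greml_univariate(design, grm_full)
  y <- design$Y[, 1]
  X <- design$X
  map <- geno$map
  chrom <- map$chrom
  unmapped <- is.na(chrom) | chrom %in% c("0", "Un", "unknown")
  S <- geno$dosage
  p2 <- colMeans(S, na.rm = TRUE) / 2
  Smi <- sweep(S, 2L, 2 * p2)        # mean-imputed, centred dosages
  Smi[is.na(Smi)] <- 0
  res <- data.frame(snp_id = map$snp_id, chrom = chrom, pos = map$pos,
                    freq = p2, alpha = NA_real_, se = NA_real_,
                    chi2 = NA_real_, p = NA_real_,
                    loco = !unmapped, stringsAsFactors = FALSE)
  test_block <- function(cols, G, sg, se) {
    ee <- eigen(G, symmetric = TRUE)
    d <- pmax(ee$values, 0)
    w <- 1 / (sg * d + se)
    Xt <- crossprod(ee$vectors, X)
    yt <- as.numeric(crossprod(ee$vectors, y))
    Cinv <- solve(crossprod(Xt, w * Xt))
    Pv <- function(v) w * v - (w * Xt) %*% (Cinv %*% crossprod(Xt, w * v))
    Py <- as.numeric(Pv(yt))
    St <- crossprod(ee$vectors, Smi[, cols, drop = FALSE])
    PS <- w * St - (w * Xt) %*% (Cinv %*% crossprod(Xt, w * St))
    sPs <- colSums(St * PS)
    sPy <- as.numeric(crossprod(St, Py))
    a <- sPy / sPs
    se_a <- sqrt(1 / sPs)
    cbind(alpha = a, se = se_a)
  }
  chroms <- unique(chrom[!unmapped])
  for (cc in chroms) {
    on_c <- which(chrom == cc)
    off_c <- which(!unmapped & chrom != cc)
    if (!length(off_c))
      stop("chromosome ", cc, " holds all mapped SNPs; LOCO GRM would be empty")
    g_off <- genotype_matrix(S[, off_c, drop = FALSE],
                             map[off_c, , drop = FALSE])
    grm_off <- compute_grm(g_off)
    if (per_chrom_vc) {
      vc_c <- fit_greml_univariate(design, grm_off)
      sg <- vc_c$sigma2_g; sev <- vc_c$sigma2_e
    } else {
      sg <- vc$sigma2_g; sev <- vc$sigma2_e
    }
    est <- test_block(on_c, grm_off$values, sg, sev)
    res$alpha[on_c] <- est[, "alpha"]
    res$se[on_c] <- est[, "se"]
  }
  if (any(unmapped)) {
    est <- test_block(which(unmapped), grm_full$values,
                      vc$sigma2_g, vc$sigma2_e)
    res$alpha[unmapped] <- est[, "alpha"]
    res$se[unmapped] <- est[, "se"]
  }
  res$chi2 <- (res$alpha / res$se)^2
  res$p <- pchisq(res$chi2, df = 1, lower.tail = FALSE)
  n_mapped <- sum(!unmapped)
  thr <- bonferroni_thresholds(nrow(res),
                               max(1, round(n_mapped / max(1, length(chroms)))),
                               alpha)
  structure(list(snps = res, lambda = inflation_factor(res$chi2),
                 thresholds = thr, vc = vc, n = length(ids)),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("GWAS: %d SNPs, n = %d, lambda = %.3f\n",
              nrow(x$snps), x$n, x$lambda))
  cat(sprintf("  thresholds: genome-wide p <= %.2e (-log10 = %.1f), chromosome-wide p <= %.2e (-log10 = %.1f)\n",
              x$thresholds$genome_wide_p, x$thresholds$genome_wide_log10,
              x$thresholds$chrom_wide_p, x$thresholds$chrom_wide_log10))
  invisible(x)
}

#' Candidate-gene window scan around top GWAS SNPs
#'
#' Selects the `top_k` SNPs with smallest p (ties broken by ascending
#' chromosome, position, then SNP id) and reports every annotated gene whose
#' interval intersects `[pos - window, pos + window]` (1-based inclusive on
#' both ends; the lower bound is clipped at 1) on the same chromosome.
#'
#' @param result `gwas_result`.
#' @param annotation `annotation_index` data.frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param top_k number of top SNPs (default 10).
#' @param window half-width in bp (default 200,000).
#' @return data.frame with one row per (SNP, gene) hit: `snp_id`, `chrom`,
#'   `pos`, `p`, `gene_id`, `gene_name`, `start`, `end`, `distance` (0 when
#'   the SNP lies inside the gene).
#' @export
candidate_gene_scan <- function(result, annotation, top_k = 10,
                                window = 200000) {
  snps <- result$snps
  snps <- snps[!is.na(snps$p), , drop = FALSE]
  ord <- order(snps$p, snps$chrom, snps$pos, snps$snp_id)
  top <- snps[ord[seq_len(min(top_k, nrow(snps)))], , drop = FALSE]
  top_gr <- GenomicRanges::GRanges(
    seqnames = top$chrom,
    ranges = IRanges::IRanges(start = pmax(1, top$pos - window),
                              end = top$pos + window))
  ann_gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end))
  hits <- GenomicRanges::findOverlaps(top_gr, ann_gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    snp_id = top$snp_id[qi], chrom = top$chrom[qi], pos = top$pos[qi],
    p = top$p[qi],
    gene_id = annotation$gene_id[si],
    gene_name = if ("gene_name" %in% names(annotation))
      annotation$gene_name[si] else annotation$gene_id[si],
    start = annotation$start[si], end = annotation$end[si],
    stringsAsFactors = FALSE)
  out$distance <- pmax(0, pmax(out$start - out$pos, out$pos - out$end))
  out[order(out$p, out$snp_id, out$start), , drop = FALSE]
}

#' Export Manhattan and Q-Q plot tables
#'
#' The Manhattan table carries a cumulative genome coordinate (chromosomes
#' laid end to end in label order, unmapped SNPs appended last) and -log10 p;
#' the Q-Q table pairs sorted observed -log10 p with expected quantiles
#' `-log10((i - 0.5) / m)`.
#'
#' @param result `gwas_result`.
#' @return list with data.frames `manhattan` (`snp_id`, `chrom`, `pos`,
#'   `cum_pos`, `neg_log10_p`) and `qq` (`expected`, `observed`).
#' @export
export_plots_data <- function(result) {
  snps <- result$snps[!is.na(result$snps$p), , drop = FALSE]
  if (!nrow(snps)) stop("empty GWAS result")
  chrom_lab <- ifelse(snps$loco, snps$chrom, "unplaced")
  num <- suppressWarnings(as.numeric(chrom_lab))
  lev <- unique(chrom_lab[order(is.na(num), num, chrom_lab)])
  ord <- order(match(chrom_lab, lev), snps$pos)
  snps <- snps[ord, , drop = FALSE]
  chrom_lab <- chrom_lab[ord]
  offset <- 0
  cum <- numeric(nrow(snps))
  for (cc in lev) {
    idx <- which(chrom_lab == cc)
    cum[idx] <- snps$pos[idx] + offset
    offset <- offset + max(snps$pos[idx])
  }
  manhattan <- data.frame(snp_id = snps$snp_id, chrom = chrom_lab,
                          pos = snps$pos, cum_pos = cum,
                          neg_log10_p = -log10(snps$p),
                          stringsAsFactors = FALSE)
  m <- nrow(snps)
  obs <- sort(-log10(snps$p), decreasing = TRUE)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m), observed = obs)
  list(manhattan = manhattan, qq = qq)
}
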