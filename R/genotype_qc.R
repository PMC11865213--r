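#' Construct a genotype matrix
#'
#' Container for a sample x SNP dosage matrix coded 0 = AA, 1 = AB|BA,
#' 2 = BB (count of the second allele), `NA` = missing, together with the
#' SNP map (chromosome label, 1-based position, alleles).
#'
#' @param dosage numeric/integer matrix, samples in rows (rownames = sample
#'   ids), SNPs in columns (colnames = SNP ids).
#' @param map data.frame with at least `snp_id`, `chrom`, `pos`; one row per
#'   column of `dosage`, in the same order.
#' @return object of class `genotype_matrix` with elements `dosage`, `map`.
#' @export
genotype_matrix <- function(dosage, map) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix")
  if (nrow(map) != ncol(dosage)) stop("map rows must match dosage columns")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage needs sample ids (rownames) and SNP ids (colnames)")
  if (!identical(map$snp_id, colnames(dosage)))
    stop("map snp_id must match dosage column names")
  if (anyDuplicated(map$snp_id)) stop("snp ids must be unique")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing")
  if (any(map$pos < 1, na.rm = TRUE)) stop("positions must be >= 1")
  if (!"qc_violation" %in% names(map)) map$qc_violation <- "none"
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Subset a genotype matrix by sample ids
#'
#' @param genotypes `genotype_matrix`.
#' @param sample_ids character vector of sample ids to keep (order preserved).
#' @return `genotype_matrix` restricted to those samples.
#' @export
subset_samples <- function(genotypes, sample_ids) {
  missing <- setdiff(sample_ids, rownames(genotypes$dosage))
  if (length(missing))
    stop("unknown sample ids: ", paste(head(missing, 5), collapse = ", "))
  genotype_matrix(genotypes$dosage[sample_ids, , drop = FALSE], genotypes$map)
}

#' Per-SNP quality-control metrics
#'
#' Computes, for every SNP: the call rate (non-missing fraction), the minor
#' allele frequency `min(p, 1-p)` with `p` the second-allele frequency among
#' non-missing calls, and a Hardy-Weinberg p-value from the 1-df Pearson
#' chi-square of observed versus expected genotype counts under `p` (no
#' continuity correction).  SNPs with fewer than two non-missing calls get
#' undefined (`NA`) metrics and fail.  Monomorphic SNPs are assigned a HWE
#' p-value of 1 (no testable departure); they fail on the MAF filter instead.
#'
#' @param genotypes `genotype_matrix`.
#' @param thresholds named list/vector with `call_rate`, `maf`, `hwe_p`; a
#'   SNP passes when it strictly exceeds all three.
#' @return data.frame (class `snp_qc_report`) with columns `snp_id`,
#'   `call_rate`, `maf`, `hwe_p`, `pass`; per-filter failure indicators are
#'   in columns `fail_call_rate`, `fail_maf`, `fail_hwe`.
#' @export
snp_metrics <- function(genotypes,
                        thresholds = list(call_rate = 0.9, maf = 0.02,
                                          hwe_p = 0.001)) {
  S <- genotypes$dosage
  n <- nrow(S)
  n0 <- colSums(S == 0, na.rm = TRUE)
  n1 <- colSums(S == 1, na.rm = TRUE)
  n2 <- colSums(S == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  call_rate <- nn / n
  p <- ifelse(nn > 0, (n1 + 2 * n2) / (2 * nn), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_chisq_p(n0, n1, n2)
  undef <- nn < 2
  call_rate[undef & nn == 0] <- 0
  maf[undef] <- NA_real_
  hwe_p[undef] <- NA_real_
  fail_cr <- !(call_rate > thresholds$call_rate)
  fail_maf <- is.na(maf) | !(maf > thresholds$maf)
  fail_hwe <- is.na(hwe_p) | !(hwe_p > thresholds$hwe_p)
  rep <- data.frame(snp_id = colnames(S),
                    call_rate = call_rate, maf = maf, hwe_p = hwe_p,
                    fail_call_rate = fail_cr, fail_maf = fail_maf,
                    fail_hwe = fail_hwe,
                    pass = !(fail_cr | fail_maf | fail_hwe),
                    stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  attr(rep, "thresholds") <- thresholds
  attr(rep, "removals") <- c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                             hwe = sum(fail_hwe), total = sum(!rep$pass))
  class(rep) <- c("snp_qc_report", "data.frame")
  rep
}

# 1-df Pearson chi-square HWE test from genotype counts (vectorised)
hwe_chisq_p <- function(n0, n1, n2) {
  nn <- n0 + n1 + n2
  p <- ifelse(nn > 0, (n1 + 2 * n2) / (2 * nn), NA_real_)
  e0 <- nn * (1 - p)^2; e1 <- nn * 2 * p * (1 - p); e2 <- nn * p^2
  chi2 <- ifelse(p <= 0 | p >= 1, 0,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  ifelse(is.na(p), NA_real_, pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Apply SNP quality-control filters
#'
#' Removes every SNP that does not strictly exceed all thresholds (defaults:
#' call rate > 0.9, MAF > 0.02, HWE p > 0.001).  A SNP failing several
#' filters is counted once per filter and once in the overall total (see the
#' `removals` attribute of the report).
#'
#' @param genotypes `genotype_matrix`.
#' @param thresholds named list with `call_rate`, `maf`, `hwe_p`.
#' @return list with `genotypes` (matrix restricted to passing SNPs) and
#'   `report` (the `snp_qc_report` of the input panel).
#' @export
apply_qc <- function(genotypes,
                     thresholds = list(call_rate = 0.9, maf = 0.02,
                                       hwe_p = 0.001)) {
  rep <- snp_metrics(genotypes, thresholds)
  keep <- which(rep$pass)
  if (!length(keep))
    stop("all SNPs removed by QC: empty panel")
  filtered <- genotype_matrix(genotypes$dosage[, keep, drop = FALSE],
                              genotypes$map[keep, , drop = FALSE])
  list(genotypes = filtered, report = rep)
}
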