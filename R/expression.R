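#' Normalise a fragment-count matrix to log2 FPKM
#'
#' Library sizes are normalised with median-of-ratios size factors: for each
#' sample, the size factor is the median over reference genes (genes with a
#' positive count in every sample) of count / geometric mean of that gene's
#' counts.  FPKM is then `count * 1e9 / (length * normalized library size)`
#' where the normalised library size is the sample's total count divided by
#' its size factor, and `log2(FPKM + 1)` is stored for downstream modelling.
#'
#' @param counts gene x sample matrix of non-negative integer fragment
#'   counts (rownames = gene ids, colnames = sample ids).
#' @param lengths per-gene transcript length in bp (named or in row order).
#' @return object of class `expression_matrix`: `counts`, `lengths`,
#'   `size_factors`, `fpkm`, `log2_fpkm`.
#' @export
normalize_expression <- function(counts, lengths) {
  if (ncol(counts) < 2) stop("need at least two samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(lengths < 1)) stop("gene lengths must be >= 1 bp")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  ref <- rowSums(counts > 0) == ncol(counts)   # genes expressed everywhere
  if (!any(ref)) stop("no reference genes for size-factor estimation")
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2L,
              function(cnt) exp(median(log(cnt) - loggeo)))
  # normalised library size: the size factor times the common depth scale,
  # so sequencing depth cancels out of FPKM
  libsize <- sf * exp(mean(log(tot / sf)))
  fpkm <- sweep(counts * 1e9 / lengths, 2L, libsize, "/")
  structure(list(counts = counts, lengths = lengths, size_factors = sf,
                 fpkm = fpkm, log2_fpkm = log2(fpkm + 1)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (size factors %.2f-%.2f)\n",
              nrow(x$counts), ncol(x$counts),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' Per-gene trait-expression linear mixed model
#'
#' Fits `trait = b0 + b1 * expression + sex + family + error` where family is
#' a full-sib random intercept, by restricted maximum likelihood profiling
#' the family-to-residual variance ratio.  With most families represented by
#' a single fish the family variance frequently hits zero, in which case the
#' fit reduces exactly to ordinary least squares.  The reported p-value for
#' the regression coefficient `b1` is a Wald test against the standard
#' normal (`reference = "normal"`, as for a large-sample chi-square) or the
#' t distribution with residual degrees of freedom (`reference = "t"`).
#'
#' @param trait numeric response per sample (liver fat %).
#' @param expr numeric explanatory expression value per sample (log2 FPKM).
#' @param sex factor/character of sex labels.
#' @param family factor/character of full-sib family labels.
#' @param reference `"normal"` or `"t"` reference for the Wald p-value.
#' @param ratio optional fixed family-to-residual variance ratio (skips
#'   profiling; `ratio = 0` forces the OLS limit).
#' @return list (class `gene_assoc`) with `beta1`, `se_beta1`, `p_value`,
#'   `significant` (p < 0.05), `beta0`, `sigma2_e`, `sigma2_family`,
#'   `ratio`.
#' @export
fit_gene_trait_lmm <- function(trait, expr, sex, family,
                               reference = c("normal", "t"), ratio = NULL) {
  reference <- match.arg(reference)
  ok <- complete.cases(trait, expr, sex, family)
  y <- trait[ok]; x <- expr[ok]
  sexf <- factor(sex[ok]); famf <- factor(family[ok])
  n <- length(y)
  if (length(unique(x)) < 3)
    stop("undefined slope: fewer than 3 distinct expression values")
  X <- cbind(intercept = 1, expr = x)
  if (nlevels(sexf) > 1)
    X <- cbind(X, stats::model.matrix(~sexf)[, -1, drop = FALSE])
  p <- ncol(X)
  # rotate into the eigenbasis of the family incidence crossproduct
  Zf <- stats::model.matrix(~famf - 1)
  Fm <- tcrossprod(Zf)
  ef <- eigen(Fm, symmetric = TRUE)
  lam <- pmax(ef$values, 0)
  yt <- as.numeric(crossprod(ef$vectors, y))
  Xt <- crossprod(ef$vectors, X)
  prof <- function(lr) {          # profiled REML criterion at ratio exp(lr)
    v <- 1 + exp(lr) * lam
    w <- 1 / v
    XtWX <- crossprod(Xt, w * Xt)
    b <- solve(XtWX, crossprod(Xt, w * yt))
    r <- yt - as.numeric(Xt %*% b)
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    0.5 * (sum(log(v)) + (n - p) * log(s2) + determinant(XtWX)$modulus)
  }
  if (is.null(ratio)) {
    opt <- optimize(prof, c(-12, 8))
    ratio <- if (prof(-40) <= opt$objective + 1e-10) 0 else exp(opt$minimum)
  }
  v <- 1 + ratio * lam
  w <- 1 / v
  XtWX <- crossprod(Xt, w * Xt)
  Cinv <- solve(XtWX)
  b <- as.numeric(Cinv %*% crossprod(Xt, w * yt))
  r <- yt - as.numeric(Xt %*% b)
  s2 <- sum(w * r^2) / (n - p)
  se <- sqrt(s2 * diag(Cinv))
  z <- b[2] / se[2]
  pval <- if (reference == "normal") 2 * pnorm(-abs(z))
          else 2 * pt(-abs(z), df = n - p)
  structure(list(beta1 = unname(b[2]), se_beta1 = unname(se[2]),
                 p_value = unname(pval),
                 significant = unname(pval < 0.05), beta0 = unname(b[1]),
                 sigma2_e = s2, sigma2_family = ratio * s2, ratio = ratio),
            class = "gene_assoc")
}

#' Trait-expression association scan over all retained genes
#'
#' Applies an expression filter (by default FPKM > 0 in at least 50% of
#' samples), then fits \code{\link{fit_gene_trait_lmm}} for every retained
#' gene with the trait as response and log2 FPKM as explanatory variable.
#' Genes are called significantly trait-associated at raw p < 0.05 — no
#' multiple-testing correction, matching the published analysis convention.
#' Genes with (near-)constant expression are skipped and reported with `NA`.
#'
#' @param expr `expression_matrix` (see \code{\link{normalize_expression}}).
#' @param phenotypes data.frame with `individual_id`, the trait, `sex` and
#'   `family_id`.
#' @param trait trait column name (default `"liver_fat"`).
#' @param min_expressed_fraction retention filter: fraction of samples in
#'   which a gene must have FPKM > 0.
#' @param reference Wald reference, see \code{\link{fit_gene_trait_lmm}}.
#' @return data.frame (class `gene_assoc_table`) with one row per retained
#'   gene: `gene_id`, `beta1`, `se_beta1`, `p_value`, `significant`.
#' @export
run_association_scan <- function(expr, phenotypes, trait = "liver_fat",
                                 min_expressed_fraction = 0.5,
                                 reference = "normal") {
  ids <- intersect(colnames(expr$counts), phenotypes$individual_id)
  if (!length(ids)) stop("no overlapping samples between expression and phenotypes")
  ph <- phenotypes[match(ids, phenotypes$individual_id), , drop = FALSE]
  fpkm <- expr$fpkm[, ids, drop = FALSE]
  l2 <- expr$log2_fpkm[, ids, drop = FALSE]
  keep <- rowMeans(fpkm > 0) >= min_expressed_fraction
  if (!any(keep)) {
    warning("no genes pass the expression filter; empty result")
    return(structure(data.frame(gene_id = character(0), beta1 = numeric(0),
                                se_beta1 = numeric(0), p_value = numeric(0),
                                significant = logical(0)),
                     class = c("gene_assoc_table", "data.frame")))
  }
  genes <- rownames(l2)[keep]
  y <- ph[[trait]]
  out <- lapply(genes, function(g) {
    fit <- tryCatch(
      fit_gene_trait_lmm(y, l2[g, ], ph$sex, ph$family_id,
                         reference = reference),
      error = function(e) NULL)
    if (is.null(fit))
      data.frame(gene_id = g, beta1 = NA_real_, se_beta1 = NA_real_,
                 p_value = NA_real_, significant = NA,
                 stringsAsFactors = FALSE)
    else
      data.frame(gene_id = g, beta1 = fit$beta1, se_beta1 = fit$se_beta1,
                 p_value = fit$p_value, significant = fit$significant,
                 stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gene_assoc_table", "data.frame")
  res
}
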