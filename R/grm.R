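#' Compute the VanRaden genomic relationship matrix
#'
#' Builds `G = Z Z' / (2 * sum_i p_i (1 - p_i))` where `Z = S - 2p` is the
#' column-centred dosage matrix and `p_i` the second-allele frequency of SNP
#' `i` computed from the analysed sample.  Missing dosages are mean-imputed
#' to `2 p_i` before centring, i.e. they contribute zero to `Z`.
#'
#' @param genotypes post-QC `genotype_matrix`; every SNP must be polymorphic.
#' @return object of class `grmatrix`: list with `values` (symmetric n x n
#'   matrix with sample ids as dimnames), `sample_ids`, `n_snps_used`,
#'   `denominator`, `p` (per-SNP frequencies).
#' @export
compute_grm <- function(genotypes) {
  S <- genotypes$dosage
  p <- colMeans(S, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("monomorphic or all-missing SNP encountered; run apply_qc first")
  Z <- sweep(S, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  structure(list(values = G, sample_ids = rownames(S),
                 n_snps_used = ncol(S), denominator = denom, p = p),
            class = "grmatrix")
}

#' @export
print.grmatrix <- function(x, ...) {
  cat(sprintf("grmatrix: %d samples, %d SNPs (mean diagonal %.3f)\n",
              length(x$sample_ids), x$n_snps_used, mean(diag(x$values))))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Top-k eigenvectors of G scaled by the square root of their eigenvalues.
#' Sign convention: within each component the loading of largest magnitude
#' is made positive, so results are deterministic.
#'
#' @param grm `grmatrix`.
#' @param k number of components (0 < k < n).
#' @return n x k matrix of sample coordinates (rownames = sample ids).
#' @export
grm_pca <- function(grm, k = 2) {
  n <- length(grm$sample_ids)
  if (k <= 0) stop("k must be a positive integer")
  if (k >= n) stop("k must be smaller than the number of samples")
  ee <- eigen(grm$values, symmetric = TRUE)
  ev <- pmax(ee$values[seq_len(k)], 0)
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- sweep(V, 2L, sqrt(ev), "*")
  dimnames(coords) <- list(grm$sample_ids, paste0("PC", seq_len(k)))
  coords
}

#' Write a genomic relationship matrix to disk
#'
#' Two dialects: `"binary"` writes the row-major lower triangle (diagonal
#' included) as 4-byte little-endian floats to `<prefix>.grm.bin`, with the
#' sample ids in the sidecar `<prefix>.grm.id` (one id per line); `"tsv"`
#' writes the full matrix as a tab-separated table with header to
#' `<prefix>.grm.tsv`.
#'
#' @param grm `grmatrix`.
#' @param prefix path prefix for the output files.
#' @param format `"binary"` or `"tsv"`.
#' @return invisibly, the paths written.
#' @export
write_grm <- function(grm, prefix, format = c("binary", "tsv")) {
  format <- match.arg(format)
  G <- grm$values
  n <- nrow(G)
  if (format == "binary") {
    bin <- paste0(prefix, ".grm.bin")
    idf <- paste0(prefix, ".grm.id")
    # column-major upper triangle == row-major lower triangle for symmetric G
    tri <- G[upper.tri(G, diag = TRUE)]
    con <- file(bin, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.numeric(tri), con, size = 4L, endian = "little")
    writeLines(grm$sample_ids, idf)
    invisible(c(bin, idf))
  } else {
    tsv <- paste0(prefix, ".grm.tsv")
    df <- data.frame(sample_id = rownames(G), G, check.names = FALSE)
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(tsv)
  }
}

#' Read a genomic relationship matrix written by [write_grm()]
#'
#' @param prefix path prefix used when writing.
#' @param format `"binary"` or `"tsv"`.
#' @return `grmatrix` (with `n_snps_used` unknown, `NA`).
#' @export
read_grm <- function(prefix, format = c("binary", "tsv")) {
  format <- match.arg(format)
  if (format == "binary") {
    bin <- paste0(prefix, ".grm.bin")
    idf <- paste0(prefix, ".grm.id")
    ids <- readLines(idf)
    n <- length(ids)
    expected <- n * (n + 1) / 2
    sz <- file.info(bin)$size
    if (is.na(sz) || sz != 4 * expected)
      stop(sprintf("GRM format error: %d ids imply %d triangle records, file has %s bytes",
                   n, expected, format(sz)))
    con <- file(bin, "rb")
    on.exit(close(con), add = TRUE)
    tri <- readBin(con, "numeric", n = expected, size = 4L, endian = "little")
    G <- matrix(0, n, n, dimnames = list(ids, ids))
    G[upper.tri(G, diag = TRUE)] <- tri
    G <- G + t(G) - diag(diag(G))
  } else {
    df <- read.table(paste0(prefix, ".grm.tsv"), header = TRUE, sep = "\t",
                     check.names = FALSE)
    ids <- df$sample_id
    G <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(G) != ncol(G) || !identical(colnames(G), ids))
      stop("GRM format error: TSV ids do not match matrix dimensions")
    dimnames(G) <- list(ids, ids)
  }
  structure(list(values = G, sample_ids = ids, n_snps_used = NA_integer_,
                 denominator = NA_real_, p = NULL),
            class = "grmatrix")
}
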