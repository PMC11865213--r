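#' Yates-corrected chi-square test for a 2x2 table
#'
#' `chi2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped to zero
#' when the continuity correction exceeds `|ad - bc|`; the p-value is the
#' 1-df chi-square survival function.
#'
#' @param a,b,c,d non-negative cell counts (row-wise: a,b / c,d).
#' @return list with `chi2` and `p`.
#' @export
yates_chi_square <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("undefined test: a table margin is zero")
  num <- abs(a * d - b * c) - n / 2
  chi2 <- if (num <= 0) 0 else n * num^2 / prod(margins)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Term enrichment among trait-associated genes
#'
#' For every functional term, builds the 2x2 table (in term / not in term) x
#' (significant / not significant) over the background gene set and applies
#' the Yates-corrected chi-square test.  Terms with fewer than five
#' background genes are skipped (no p-value); terms are called enriched at
#' p < 0.05 when the significant set is over-represented.
#'
#' @param significant_genes character vector, must be a subset of
#'   `background`.
#' @param background character vector of all analysed genes.
#' @param term_map data.frame with columns `gene_id`, `term_id`.
#' @param min_term_genes minimum number of background genes per term
#'   (default 5).
#' @return data.frame (class `enrichment_table`): `term_id`, `n_term_sig`,
#'   `n_term_bg`, `chi2`, `p_value`, `enriched`, `skipped`.
#' @export
enrich_terms <- function(significant_genes, background, term_map,
                         min_term_genes = 5) {
  background <- unique(background)
  if (!length(background)) stop("empty background gene set")
  significant_genes <- unique(significant_genes)
  if (!all(significant_genes %in% background))
    stop("significant genes must be a subset of the background")
  n_sig <- length(significant_genes)
  n_bg <- length(background)
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- unique(tm$term_id)
  rows <- lapply(terms, function(t) {
    genes <- unique(tm$gene_id[tm$term_id == t])
    a <- sum(genes %in% significant_genes)   # in term, significant
    b <- length(genes) - a                   # in term, not significant
    cc <- n_sig - a                          # out of term, significant
    dd <- (n_bg - length(genes)) - cc
    if (length(genes) < min_term_genes)
      return(data.frame(term_id = t, n_term_sig = a, n_term_bg = length(genes),
                        chi2 = NA_real_, p_value = NA_real_, enriched = NA,
                        skipped = TRUE, stringsAsFactors = FALSE))
    test <- tryCatch(yates_chi_square(a, b, cc, dd), error = function(e) NULL)
    if (is.null(test)) {
      warning("degenerate margins for term ", t, "; skipped")
      return(data.frame(term_id = t, n_term_sig = a, n_term_bg = length(genes),
                        chi2 = NA_real_, p_value = NA_real_, enriched = NA,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    over <- a / length(genes) > n_sig / n_bg
    data.frame(term_id = t, n_term_sig = a, n_term_bg = length(genes),
               chi2 = test$chi2, p_value = test$p,
               enriched = test$p < 0.05 && over, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation on average ranks (midranks for ties); the p-value uses
#' the t approximation `t = rho sqrt((n-2)/(1-rho^2))` with n-2 degrees of
#' freedom (two-sided), and is 0/1-saturated at |rho| = 1.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Hepatosomatic index
#'
#' Liver weight as a percentage of body weight:
#' `(liver_weight / body_weight) * 100`.  Both weights must be on the same
#' scale (e.g. grams).
#'
#' @param liver_weight numeric (>= 0).
#' @param body_weight numeric (> 0).
#' @return HSI value(s).
#' @export
hepatosomatic_index <- function(liver_weight, body_weight) {
  if (any(body_weight <= 0, na.rm = TRUE))
    stop("body weight must be positive")
  (liver_weight / body_weight) * 100
}

#' Reverse a 1-5 liver colour score
#'
#' Maps score `s` to `6 - s`, so that after reversal a higher score means a
#' fattier (lighter-coloured) liver.  An involution on {1,...,5}.
#'
#' @param score integer vector with values in 1..5.
#' @return reversed score.
#' @export
reverse_liver_score <- function(score) {
  if (any(!score %in% 1:5))
    stop("liver score must be an integer in 1..5")
  6L - as.integer(score)
}

#' Descriptive statistics of phenotype columns
#'
#' Per column: number of non-missing values, mean, SD, min, max.  A single
#' observation yields SD 0 with a warning.
#'
#' @param phenotypes data.frame.
#' @param columns character vector of numeric column names (default: all
#'   numeric columns).
#' @return data.frame with columns `variable`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
descriptive_stats <- function(phenotypes, columns = NULL) {
  if (is.null(columns))
    columns <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
  rows <- lapply(columns, function(cl) {
    v <- phenotypes[[cl]]
    if (!is.numeric(v)) stop("column is not numeric: ", cl)
    v <- v[!is.na(v)]
    s <- if (length(v) > 1) sd(v) else {
      warning("single observation for ", cl, "; SD reported as 0")
      0
    }
    data.frame(variable = cl, n = length(v), mean = mean(v), sd = s,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
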