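#' Build a mixed-model design from a phenotype table
#'
#' Aligns phenotype records to the samples of a genomic relationship matrix
#' and assembles the response and fixed-effect design (intercept, sex, and
#' optional extra numeric covariates such as GRM principal components).
#'
#' @param phenotypes data.frame with `individual_id`, the trait column(s) and
#'   covariate columns.
#' @param traits character vector of one or two trait column names.
#' @param covariates character vector of covariate column names (factors are
#'   expanded via `model.matrix`); default `"sex"`.
#' @param extra optional numeric matrix of additional covariates with sample
#'   ids as rownames (e.g. output of \code{\link{grm_pca}}).
#' @param sample_ids samples to keep, in this order (default: all phenotype
#'   rows).  Records with a missing response in every trait are dropped.
#' @return list of class `model_design` with `Y` (n x n_traits matrix), `X`
#'   (n x p full-column-rank design), `sample_ids`.
#' @export
model_design <- function(phenotypes, traits, covariates = "sex",
                         extra = NULL, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- phenotypes$individual_id
  idx <- match(sample_ids, phenotypes$individual_id)
  if (anyNA(idx)) stop("phenotypes missing for some requested samples")
  ph <- phenotypes[idx, , drop = FALSE]
  Y <- as.matrix(ph[, traits, drop = FALSE])
  mode(Y) <- "numeric"
  keep <- rowSums(!is.na(Y)) > 0
  ph <- ph[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  X <- matrix(1, nrow(ph), 1, dimnames = list(NULL, "intercept"))
  for (cv in covariates) {
    v <- ph[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (is.numeric(v)) {
      X <- cbind(X, setNames(data.frame(v), cv))
      X <- as.matrix(X)
    } else {
      mm <- stats::model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, "_", levels(factor(v))[-1])
      X <- cbind(X, mm)
    }
  }
  if (!is.null(extra)) {
    ex <- extra[ph$individual_id, , drop = FALSE]
    X <- cbind(X, ex)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("fixed-effect design is rank deficient")
  structure(list(Y = Y, X = X, sample_ids = ph$individual_id),
            class = "model_design")
}

#' Restricted log-likelihood of the univariate animal model
#'
#' Evaluates (up to an additive constant) the REML log-likelihood
#' `-0.5 [ log|V| + log|X'V^-1 X| + y'Py ]` of
#' `y ~ N(X b, G sigma2_g + I sigma2_e)` at given variance components.
#' Useful for grid checks of the optimiser.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix.
#' @param G relationship matrix (or `grmatrix`).
#' @param sigma2_g,sigma2_e variance components (> 0).
#' @return scalar restricted log-likelihood (constant omitted).
#' @export
reml_loglik <- function(y, X, G, sigma2_g, sigma2_e) {
  if (inherits(G, "grmatrix")) G <- G$values
  ee <- eigen(G, symmetric = TRUE)
  yt <- crossprod(ee$vectors, y)
  Xt <- crossprod(ee$vectors, X)
  uni_loglik(as.numeric(yt), Xt, ee$values, sigma2_g, sigma2_e)$loglik
}

# loglik and intermediates in the rotated (eigen) basis
uni_loglik <- function(yt, Xt, d, sg, se) {
  v <- sg * d + se
  if (any(v <= 0)) return(list(loglik = -Inf))
  w <- 1 / v
  XtWX <- crossprod(Xt, w * Xt)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  Cinv <- chol2inv(ch)
  beta <- Cinv %*% crossprod(Xt, w * yt)
  r <- yt - as.numeric(Xt %*% beta)
  Py <- w * r
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + sum(r * Py))
  list(loglik = ll, w = w, Py = Py, Cinv = Cinv, beta = beta, r = r)
}

#' Univariate GREML fit by average-information REML
#'
#' Maximises the restricted likelihood of the animal model
#' `y = X b + u + e`, `u ~ N(0, G sigma2_g)`, `e ~ N(0, I sigma2_e)` using an
#' EM-REML first step followed by average-information updates with
#' step-halving (accepted steps never decrease the restricted likelihood).
#' The GRM is eigendecomposed once, so every iteration costs O(n p^2).
#' Components are constrained to at least `1e-8` times the phenotypic
#' variance; hitting that bound sets `boundary = TRUE`.  Standard errors come
#' from the inverse average-information matrix and SE(h2) by the delta
#' method.
#'
#' @param design `model_design` with a single trait (or a list with `Y`/`y`
#'   and `X`), samples aligned with `grm`.
#' @param grm `grmatrix` covering (at least) the design samples.
#' @param log_transform fit `log(y)` instead of `y` (sensitivity analysis for
#'   skewed traits).
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @return object of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `se_sigma2_g`, `se_sigma2_e`, `h2`, `se_h2`, `reml_loglik`,
#'   `n_iterations`, `converged`, `boundary`, `beta`.
#' @export
fit_greml_univariate <- function(design, grm, log_transform = FALSE,
                                 max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(if (!is.null(design$Y)) design$Y[, 1] else design$y)
  X <- design$X
  n <- length(y)
  if (n < 50) warning("fewer than 50 samples: variance components will be imprecise")
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires a strictly positive response")
    y <- log(y)
  }
  G <- grm$values
  if (!is.null(design$sample_ids)) {
    idx <- match(design$sample_ids, grm$sample_ids)
    if (anyNA(idx)) stop("GRM does not cover all design samples")
    G <- G[idx, idx, drop = FALSE]
  }
  ee <- eigen(G, symmetric = TRUE)
  if (min(ee$values) < -1e-6)
    stop("relationship matrix is not positive semidefinite")
  d <- pmax(ee$values, 0)
  yt <- as.numeric(crossprod(ee$vectors, y))
  Xt <- crossprod(ee$vectors, X)

  vp <- var(y)
  lb <- 1e-8 * vp
  theta <- c(sg = vp / 2, se = vp / 2)
  st <- uni_loglik(yt, Xt, d, theta[1], theta[2])
  ll <- st$loglik
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    # score and AI at current theta
    w <- st$w; Py <- st$Py; Cinv <- st$Cinv
    WX <- w * Xt
    trPG <- sum(w * d) - sum(Cinv * crossprod(Xt, (w^2 * d) * Xt))
    trPI <- sum(w) - sum(Cinv * crossprod(Xt, (w^2) * Xt))
    yPGPy <- sum(d * Py^2)
    yPIPy <- sum(Py^2)
    score <- -0.5 * c(trPG - yPGPy, trPI - yPIPy)
    Pq <- function(q) w * q - WX %*% (Cinv %*% crossprod(Xt, w * q))
    qg <- d * Py; qe <- Py
    Pqg <- Pq(qg); Pqe <- Pq(qe)
    AI <- 0.5 * matrix(c(sum(qg * Pqg), sum(qg * Pqe),
                         sum(qg * Pqe), sum(qe * Pqe)), 2, 2)
    if (iter == 1L) {
      delta <- theta^2 * c(yPGPy - trPG, yPIPy - trPI) / n   # EM-REML step
    } else {
      delta <- tryCatch(solve(AI, score),
                        error = function(e) score / max(diag(AI), 1))
    }
    step <- 1
    repeat {
      prop <- pmax(theta + step * delta, lb)
      st2 <- uni_loglik(yt, Xt, d, prop[1], prop[2])
      if (st2$loglik >= ll - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    if (st2$loglik < ll - 1e-10) { converged <- TRUE; break }  # no uphill step left
    dll <- st2$loglik - ll
    theta <- prop; st <- st2; ll <- st2$loglik
    if (abs(dll) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  Vcov <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  sg <- unname(theta[1]); se <- unname(theta[2])
  h2 <- heritability_from_components(sg, se)
  gr <- c(se, -sg) / (sg + se)^2
  se_h2 <- sqrt(max(0, drop(t(gr) %*% Vcov %*% gr)))
  structure(list(sigma2_g = sg, sigma2_e = se,
                 se_sigma2_g = sqrt(max(0, Vcov[1, 1])),
                 se_sigma2_e = sqrt(max(0, Vcov[2, 2])),
                 h2 = h2, se_h2 = se_h2,
                 reml_loglik = ll, n_iterations = iter,
                 converged = converged,
                 boundary = any(theta <= lb * (1 + 1e-12)),
                 beta = drop(st$beta), ai_vcov = Vcov),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("GREML variance components (%s, %d iterations)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  sigma2_g = %.4f (SE %.4f)\n", x$sigma2_g, x$se_sigma2_g))
  cat(sprintf("  sigma2_e = %.4f (SE %.4f)\n", x$sigma2_e, x$se_sigma2_e))
  cat(sprintf("  h2       = %.4f (SE %.4f)\n", x$h2, x$se_h2))
  if (x$boundary) cat("  note: a component is at its lower bound\n")
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' @param sigma2_g additive genetic variance (>= 0).
#' @param sigma2_e residual variance (>= 0).
#' @return `sigma2_g / (sigma2_g + sigma2_e)`.
#' @export
heritability_from_components <- function(sigma2_g, sigma2_e) {
  if (any(c(sigma2_g, sigma2_e) < 0)) stop("variance components must be >= 0")
  if (sigma2_g + sigma2_e == 0) stop("undefined ratio: both components are zero")
  sigma2_g / (sigma2_g + sigma2_e)
}

#' Coefficient of variation
#'
#' Ratio of a standard deviation to a mean; with the genetic standard
#' deviation in the numerator this is the genetic coefficient of variation.
#'
#' @param sd standard deviation (>= 0).
#' @param mean trait mean (> 0).
#' @return `sd / mean`.
#' @export
coefficient_of_variation <- function(sd, mean) {
  if (mean <= 0) stop("undefined CV: mean must be positive")
  sd / mean
}
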