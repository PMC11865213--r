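#' Bivariate GREML fit by average-information REML
#'
#' Direct extension of the univariate animal model to two traits: the
#' stacked response has covariance `Sigma_g (x) G + Sigma_e (x) I` with 2x2
#' genetic and residual (co)variance matrices.  Both matrices are estimated
#' by AI-REML with step-halving; the genetic correlation is
#' `rg = cov_g / sqrt(sigma2_g1 sigma2_g2)` with its SE by the delta method
#' from the inverse average-information matrix.  When both traits are
#' observed on every sample the GRM is eigendecomposed once and the
#' likelihood factorises into n 2x2 blocks; records missing one trait are
#' handled by a dense-likelihood path on the observed records.  Estimated
#' covariances are kept inside the positive-semidefinite cone by clamping
#' the implied correlations at +/-0.999 (flagged as `boundary`).
#'
#' @param design `model_design` with two traits (columns of `Y`); `NA` in one
#'   trait marks a record observed for the other trait only.
#' @param grm `grmatrix` covering the design samples.
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @return object of class `bivariate_components`: `Sigma_g`, `Sigma_e` (2x2
#'   matrices), per-trait `sigma2_g`, `sigma2_e`, `h2`, `rg`, `se_rg`,
#'   `reml_loglik`, `n_iterations`, `converged`, `boundary`.
#' @export
fit_greml_bivariate <- function(design, grm, max_iter = 100L, tol = 1e-8) {
  Y <- design$Y
  if (ncol(Y) != 2) stop("bivariate fit needs exactly two traits")
  for (j in 1:2)
    if (stats::sd(Y[, j], na.rm = TRUE) == 0 || all(is.na(Y[, j])))
      stop("degenerate trait: column ", j, " is constant or empty")
  idx <- match(design$sample_ids, grm$sample_ids)
  if (anyNA(idx)) stop("GRM does not cover all design samples")
  G <- grm$values[idx, idx, drop = FALSE]
  if (anyNA(Y)) {
    biv_reml_dense(Y, design$X, G, max_iter, tol)
  } else {
    biv_reml_eigen(Y, design$X, G, max_iter, tol)
  }
}

#' @export
print.bivariate_components <- function(x, ...) {
  cat(sprintf("Bivariate GREML (%s, %d iterations)\n",
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  cat(sprintf("  h2: %.3f / %.3f\n", x$h2[1], x$h2[2]))
  cat(sprintf("  rg = %.3f (SE %.3f)\n", x$rg, x$se_rg))
  if (x$boundary) cat("  note: estimate at a constraint boundary\n")
  invisible(x)
}

# shared post-processing: SEs, rg, result object
biv_result <- function(theta, AI, ll, iter, converged, boundary) {
  Vcov <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 6, 6))
  Sg <- matrix(theta[c(1, 2, 2, 3)], 2, 2)
  Se <- matrix(theta[c(4, 5, 5, 6)], 2, 2)
  rg <- theta[2] / sqrt(theta[1] * theta[3])
  rg_cl <- max(-1, min(1, rg))
  gr <- c(-rg / (2 * theta[1]), 1 / sqrt(theta[1] * theta[3]),
          -rg / (2 * theta[3]))
  se_rg <- sqrt(max(0, drop(t(gr) %*% Vcov[1:3, 1:3] %*% gr)))
  h2 <- diag(Sg) / (diag(Sg) + diag(Se))
  structure(list(Sigma_g = Sg, Sigma_e = Se,
                 sigma2_g = diag(Sg), sigma2_e = diag(Se), h2 = h2,
                 rg = rg_cl, se_rg = se_rg,
                 reml_loglik = ll, n_iterations = iter,
                 converged = converged,
                 boundary = boundary || abs(rg) >= 0.999,
                 ai_vcov = Vcov),
            class = "bivariate_components")
}

# clamp a theta proposal into the PSD cone (correlations at most 0.999)
biv_clamp <- function(theta, lb) {
  theta[c(1, 3, 4, 6)] <- pmax(theta[c(1, 3, 4, 6)], lb)
  cap_g <- 0.999 * sqrt(theta[1] * theta[3])
  cap_e <- 0.999 * sqrt(theta[4] * theta[6])
  theta[2] <- max(-cap_g, min(cap_g, theta[2]))
  theta[5] <- max(-cap_e, min(cap_e, theta[5]))
  theta
}

# ---- eigen-factorised path (complete data) --------------------------------

biv_eigen_state <- function(theta, y1, y2, Xt, d) {
  p <- ncol(Xt)
  v11 <- theta[1] * d + theta[4]
  v12 <- theta[2] * d + theta[5]
  v22 <- theta[3] * d + theta[6]
  det <- v11 * v22 - v12^2
  if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0))
    return(list(loglik = -Inf))
  w11 <- v22 / det; w12 <- -v12 / det; w22 <- v11 / det
  M <- rbind(cbind(crossprod(Xt, w11 * Xt), crossprod(Xt, w12 * Xt)),
             cbind(crossprod(Xt, w12 * Xt), crossprod(Xt, w22 * Xt)))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  Minv <- chol2inv(ch)
  rhs <- c(crossprod(Xt, w11 * y1 + w12 * y2),
           crossprod(Xt, w12 * y1 + w22 * y2))
  beta <- Minv %*% rhs
  b1 <- beta[seq_len(p)]; b2 <- beta[p + seq_len(p)]
  r1 <- y1 - as.numeric(Xt %*% b1)
  r2 <- y2 - as.numeric(Xt %*% b2)
  Py1 <- w11 * r1 + w12 * r2
  Py2 <- w12 * r1 + w22 * r2
  ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(ch))) +
                  sum(r1 * Py1) + sum(r2 * Py2))
  list(loglik = ll, w11 = w11, w12 = w12, w22 = w22, Minv = Minv,
       Py1 = Py1, Py2 = Py2, beta = beta)
}

biv_reml_eigen <- function(Y, X, G, max_iter, tol) {
  n <- nrow(Y)
  ee <- eigen(G, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  y1 <- as.numeric(crossprod(ee$vectors, Y[, 1]))
  y2 <- as.numeric(crossprod(ee$vectors, Y[, 2]))
  Xt <- crossprod(ee$vectors, X)
  p <- ncol(Xt)
  Sp <- stats::cov(Y)
  theta <- c(Sp[1, 1] / 2, Sp[1, 2] / 2, Sp[2, 2] / 2,
             Sp[1, 1] / 2, Sp[1, 2] / 2, Sp[2, 2] / 2)
  lb <- 1e-8 * mean(diag(Sp))
  theta <- biv_clamp(theta, lb)
  st <- biv_eigen_state(theta, y1, y2, Xt, d)
  ll <- st$loglik
  converged <- FALSE; iter <- 0L; AI <- diag(6)
  for (iter in seq_len(max_iter)) {
    w11 <- st$w11; w12 <- st$w12; w22 <- st$w22
    Py1 <- st$Py1; Py2 <- st$Py2; Minv <- st$Minv
    # quadratic forms y'P dVk P y
    quad <- c(sum(d * Py1^2), 2 * sum(d * Py1 * Py2), sum(d * Py2^2),
              sum(Py1^2), 2 * sum(Py1 * Py2), sum(Py2^2))
    # tr(V^-1 dVk)
    trV <- c(sum(d * w11), 2 * sum(d * w12), sum(d * w22),
             sum(w11), 2 * sum(w12), sum(w22))
    # correction tr(Minv * X'V^-1 dVk V^-1 X) for each parameter
    trC <- numeric(6)
    for (k in 1:6) {
      f <- if (k <= 3) d else rep(1, length(d))
      mm <- switch(((k - 1) %% 3) + 1,
        list(m11 = f * w11^2, m12 = f * w11 * w12, m22 = f * w12^2),
        list(m11 = 2 * f * w11 * w12, m12 = f * (w11 * w22 + w12^2),
             m22 = 2 * f * w12 * w22),
        list(m11 = f * w12^2, m12 = f * w12 * w22, m22 = f * w22^2))
      N <- rbind(cbind(crossprod(Xt, mm$m11 * Xt), crossprod(Xt, mm$m12 * Xt)),
                 cbind(crossprod(Xt, mm$m12 * Xt), crossprod(Xt, mm$m22 * Xt)))
      trC[k] <- sum(Minv * N)
    }
    score <- -0.5 * ((trV - trC) - quad)
    # q_k = dVk P y, then AI_kl = 0.5 q_k' P q_l
    qs <- list(list(d * Py1, 0 * Py1), list(d * Py2, d * Py1),
               list(0 * Py1, d * Py2), list(Py1, 0 * Py1),
               list(Py2, Py1), list(0 * Py1, Py2))
    Papply <- function(a1, a2) {
      t1 <- w11 * a1 + w12 * a2
      t2 <- w12 * a1 + w22 * a2
      s <- Minv %*% c(crossprod(Xt, t1), crossprod(Xt, t2))
      h1 <- as.numeric(Xt %*% s[seq_len(p)])
      h2 <- as.numeric(Xt %*% s[p + seq_len(p)])
      list(t1 - (w11 * h1 + w12 * h2), t2 - (w12 * h1 + w22 * h2))
    }
    Pq <- lapply(qs, function(q) Papply(q[[1]], q[[2]]))
    AI <- matrix(0, 6, 6)
    for (k in 1:6) for (l in k:6) {
      AI[k, l] <- AI[l, k] <-
        0.5 * (sum(qs[[k]][[1]] * Pq[[l]][[1]]) +
                 sum(qs[[k]][[2]] * Pq[[l]][[2]]))
    }
    if (iter == 1L) {
      sc <- c(theta[1]^2, theta[1] * theta[3], theta[3]^2,
              theta[4]^2, theta[4] * theta[6], theta[6]^2)
      delta <- 2 * sc * score / n
    } else {
      delta <- tryCatch(solve(AI, score),
                        error = function(e) score / max(diag(AI), 1))
    }
    step <- 1
    repeat {
      prop <- biv_clamp(theta + step * delta, lb)
      st2 <- biv_eigen_state(prop, y1, y2, Xt, d)
      if (st2$loglik >= ll - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    if (st2$loglik < ll - 1e-10) { converged <- TRUE; break }
    dll <- st2$loglik - ll
    theta <- prop; st <- st2; ll <- st2$loglik
    if (abs(dll) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  biv_result(theta, AI, ll, iter, converged,
             boundary = any(theta[c(1, 3, 4, 6)] <= lb * (1 + 1e-12)))
}

# ---- dense path (records may miss one trait) ------------------------------

biv_dense_state <- function(theta, y, Xr, Gr, Ir, Tt) {
  Gpar <- matrix(theta[c(1, 2, 2, 3)], 2, 2)
  Epar <- matrix(theta[c(4, 5, 5, 6)], 2, 2)
  V <- Gpar[Tt] * Gr + Epar[Tt] * Ir
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  Vi <- chol2inv(ch)
  XtVi <- crossprod(Xr, Vi)
  M <- XtVi %*% Xr
  chM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(chM)) return(list(loglik = -Inf))
  Minv <- chol2inv(chM)
  beta <- Minv %*% (XtVi %*% y)
  r <- y - as.numeric(Xr %*% beta)
  Py <- as.numeric(Vi %*% r)
  P <- Vi - t(XtVi) %*% Minv %*% XtVi
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chM))) + sum(r * Py))
  list(loglik = ll, P = P, Py = Py, beta = beta)
}

biv_reml_dense <- function(Y, X, G, max_iter, tol) {
  n <- nrow(Y)
  obs <- which(!is.na(Y))              # column-major over the n x 2 matrix
  tr_r <- ((obs - 1) %/% n) + 1        # trait index per record
  id_r <- ((obs - 1) %% n) + 1         # sample index per record
  y <- Y[obs]
  p <- ncol(X)
  nr <- length(y)
  Xr <- matrix(0, nr, 2 * p)
  for (t in 1:2) {
    rows <- tr_r == t
    Xr[rows, (t - 1) * p + seq_len(p)] <- X[id_r[rows], , drop = FALSE]
  }
  Gr <- G[id_r, id_r, drop = FALSE]
  Ir <- (outer(id_r, id_r, "==")) * 1
  Tt <- cbind(rep(tr_r, nr), rep(tr_r, each = nr))  # 2-col index into 2x2 pars
  dV <- function(k) {                  # dV/dtheta_k as a full matrix
    E <- matrix(0, 2, 2)
    kk <- ((k - 1) %% 3) + 1
    if (kk == 1) E[1, 1] <- 1 else if (kk == 2) E[1, 2] <- E[2, 1] <- 1 else E[2, 2] <- 1
    if (k <= 3) E[Tt] * Gr else E[Tt] * Ir
  }
  dVs <- lapply(1:6, dV)
  Sp <- stats::cov(Y, use = "pairwise.complete.obs")
  if (anyNA(Sp)) Sp <- diag(diag(stats::cov(Y, use = "complete.obs")))
  theta <- c(Sp[1, 1] / 2, Sp[1, 2] / 2, Sp[2, 2] / 2,
             Sp[1, 1] / 2, Sp[1, 2] / 2, Sp[2, 2] / 2)
  lb <- 1e-8 * mean(diag(Sp))
  theta <- biv_clamp(theta, lb)
  st <- biv_dense_state(theta, y, Xr, Gr, Ir, Tt)
  ll <- st$loglik
  converged <- FALSE; iter <- 0L; AI <- diag(6)
  for (iter in seq_len(max_iter)) {
    P <- st$P; Py <- st$Py
    score <- numeric(6); q <- vector("list", 6)
    for (k in 1:6) {
      q[[k]] <- dVs[[k]] %*% Py
      score[k] <- -0.5 * (sum(P * dVs[[k]]) - sum(Py * q[[k]]))
    }
    AI <- matrix(0, 6, 6)
    Pq <- lapply(q, function(v) P %*% v)
    for (k in 1:6) for (l in k:6)
      AI[k, l] <- AI[l, k] <- 0.5 * sum(q[[k]] * Pq[[l]])
    if (iter == 1L) {
      sc <- c(theta[1]^2, theta[1] * theta[3], theta[3]^2,
              theta[4]^2, theta[4] * theta[6], theta[6]^2)
      delta <- 2 * sc * score / nr
    } else {
      delta <- tryCatch(solve(AI, score),
                        error = function(e) score / max(diag(AI), 1))
    }
    step <- 1
    repeat {
      prop <- biv_clamp(theta + step * delta, lb)
      st2 <- biv_dense_state(prop, y, Xr, Gr, Ir, Tt)
      if (st2$loglik >= ll - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    if (st2$loglik < ll - 1e-10) { converged <- TRUE; break }
    dll <- st2$loglik - ll
    theta <- prop; st <- st2; ll <- st2$loglik
    if (abs(dll) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
  }
  biv_result(theta, AI, ll, iter, converged,
             boundary = any(theta[c(1, 3, 4, 6)] <= lb * (1 + 1e-12)))
}
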