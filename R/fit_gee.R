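#' GEE for clustered binary data (exchangeable working correlation)
#'
#' Solves the generalised estimating equations with logit link and an
#' exchangeable working correlation. The working correlation is estimated
#' by the moment estimator from cross-products of standardised Pearson
#' residuals over the twin pairs (singleton clusters carry no information
#' about it); the scale is the Pearson-based estimate. Standard errors are
#' robust sandwich estimates with no small-sample correction. Coefficients
#' have a population-average (marginal) interpretation and are attenuated
#' relative to the conditional coefficients of the random-intercept model.
#'
#' With no clusters of size two the working correlation is undefined; it
#' is then fixed at 0 (with a diagnostic note) and the estimates reduce to
#' ordinary logistic regression with a heteroscedasticity-robust sandwich.
#'
#' @inheritParams fit_logistic
#' @param tol Convergence tolerance on the coefficient update.
#' @param max_iter Maximum number of Fisher-scoring iterations.
#' @return A `cluster_fit`; the working correlation and scale are stored
#'   as `rho` and `phi`.
#' @export
fit_gee_exchangeable <- function(data, covariates,
                                 cluster_col = "cluster_id", y_col = "y",
                                 tol = 1e-8, max_iter = 50L) {
  d <- prepare_design(data, covariates, cluster_col, y_col)
  ord <- order(d$cluster)
  d$y <- d$y[ord]; d$X <- d$X[ord, , drop = FALSE]
  d$cluster <- d$cluster[ord]
  sp <- split_by_size(d)
  X <- d$X; y <- d$y
  p <- ncol(X)
  n_pairs <- length(sp$p1)

  # start at the independence (logistic) estimates
  start <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- start$coefficients
  rho <- 0
  rho_note <- if (n_pairs == 0L)
    "no clusters of size 2; working correlation fixed at 0" else character()

  xs <- X[sp$s_idx, , drop = FALSE]; ys <- y[sp$s_idx]
  x1 <- X[sp$p1, , drop = FALSE]; y1 <- y[sp$p1]
  x2 <- X[sp$p2, , drop = FALSE]; y2 <- y[sp$p2]

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- inv_logit(drop(X %*% beta))
    a <- pmax(mu * (1 - mu), 1e-12)
    e <- (y - mu) / sqrt(a)
    phi <- sum(e^2) / (length(y) - p)
    if (n_pairs > 0L) {
      # no degrees-of-freedom correction: with very few pairs the usual
      # (n_pairs - p) denominator is zero or negative
      rho <- sum(e[sp$p1] * e[sp$p2]) / (n_pairs * phi)
      if (!is.finite(rho)) rho <- 0
      if (abs(rho) > 0.95) {
        # a moment estimate from a handful of pairs can leave the valid
        # range; clamping keeps the working covariance well conditioned
        rho <- sign(rho) * 0.95
        rho_note <- "working correlation at boundary"
      }
    }

    mus <- mu[sp$s_idx]; as_ <- a[sp$s_idx]
    mu1 <- mu[sp$p1]; a1 <- a[sp$p1]
    mu2 <- mu[sp$p2]; a2 <- a[sp$p2]
    # V_i = A^(1/2) R A^(1/2); closed-form inverse for 2x2 blocks
    cc <- rho * sqrt(a1 * a2)
    det <- a1 * a2 - cc^2
    v11 <- a2 / det; v12 <- -cc / det; v22 <- a1 / det
    # D_i = A_i X_i, so D'V^-1 has rows a_j * x_j weighted by V^-1
    w11 <- a1 * (a1 * v11); w12 <- a1 * a2 * v12; w22 <- a2 * (a2 * v22)
    M <- crossprod(xs * as_, xs)
    if (n_pairs > 0L) {
      M <- M + crossprod(x1 * w11, x1) + crossprod(x1 * w12, x2) +
        crossprod(x2 * w12, x1) + crossprod(x2 * w22, x2)
    }
    rs <- ys - mus
    r1 <- y1 - mu1; r2 <- y2 - mu2
    u1 <- a1 * (v11 * r1 + v12 * r2)
    u2 <- a2 * (v12 * r1 + v22 * r2)
    score <- crossprod(xs, rs)
    if (n_pairs > 0L)
      score <- score + crossprod(x1, u1) + crossprod(x2, u2)

    step <- tryCatch(drop(solve(M, score)), error = function(e) NULL)
    if (is.null(step)) break
    # damp oversized steps (relative to the current coefficient scale)
    fac <- max(abs(step) / (1 + abs(beta)))
    if (fac > 2) step <- step * (2 / fac)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    if (any(!is.finite(beta)) || max(abs(beta)) > 1e8) break
  }

  # sandwich at the solution: meat from per-cluster score contributions
  mu <- inv_logit(drop(X %*% beta))
  a <- pmax(mu * (1 - mu), 1e-12)
  mus <- mu[sp$s_idx]
  mu1 <- mu[sp$p1]; a1 <- a[sp$p1]
  mu2 <- mu[sp$p2]; a2 <- a[sp$p2]
  cc <- rho * sqrt(a1 * a2)
  det <- a1 * a2 - cc^2
  v11 <- a2 / det; v12 <- -cc / det; v22 <- a1 / det
  w11 <- a1 * (a1 * v11); w12 <- a1 * a2 * v12; w22 <- a2 * (a2 * v22)
  M <- crossprod(xs * a[sp$s_idx], xs)
  if (n_pairs > 0L)
    M <- M + crossprod(x1 * w11, x1) + crossprod(x1 * w12, x2) +
      crossprod(x2 * w12, x1) + crossprod(x2 * w22, x2)
  S_rows <- xs * (ys - mus)
  if (n_pairs > 0L) {
    r1 <- y1 - mu1; r2 <- y2 - mu2
    u1 <- a1 * (v11 * r1 + v12 * r2)
    u2 <- a2 * (v12 * r1 + v22 * r2)
    S_rows <- rbind(S_rows, x1 * u1 + x2 * u2)
  }
  B <- crossprod(S_rows)
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) {
    vc <- matrix(NA_real_, p, p)
    converged <- FALSE
  } else {
    vc <- Minv %*% B %*% Minv
    vc <- (vc + t(vc)) / 2
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  new_cluster_fit("gee",
                  coefficients = stats::setNames(beta, colnames(X)),
                  se = stats::setNames(sqrt(pmax(diag(vc), 0)),
                                       colnames(X)),
                  vcov = vc, converged = converged, n_iter = iter,
                  diagnostics = rho_note,
                  n_obs = length(y),
                  n_clusters = length(unique(d$cluster)),
                  extra = list(rho = rho, phi = phi))
}
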