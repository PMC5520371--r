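#' Random-intercept logistic regression by penalised quasi-likelihood
#'
#' PQL alternates (a) forming the working response
#' `z = eta + (y - p)/(p(1-p))` with weights `w = p(1-p)`, (b) a weighted
#' linear mixed-model solve for the fixed effects and the cluster random
#' intercepts, and (c) a REML update of the random-intercept variance on
#' the working linear mixed model (the conditional variance `1/w` is
#' treated as known, as appropriate for a binomial dispersion of 1).
#' Iteration stops when the largest absolute change of any parameter falls
#' below `tol`. Standard errors come from the final generalised
#' least-squares solve, i.e. the model-based `(X' V^-1 X)^-1`.
#'
#' PQL is known to underestimate variance components for binary data with
#' small clusters; it is included here as a study arm, not as a
#' recommended estimator.
#'
#' @inheritParams fit_logistic
#' @param tol Convergence tolerance on parameter changes.
#' @param max_iter Maximum number of outer iterations.
#' @param fix_sigma2 Optionally hold the random-intercept variance fixed
#'   (e.g. `0`, in which case PQL degenerates to ordinary IRLS and the
#'   estimates equal [fit_logistic()]).
#' @return A `cluster_fit` with `sigma2` the REML variance estimate.
#' @export
fit_glmm_pql <- function(data, covariates, cluster_col = "cluster_id",
                         y_col = "y", tol = 1e-6, max_iter = 50L,
                         fix_sigma2 = NULL) {
  d <- prepare_design(data, covariates, cluster_col, y_col)
  ord <- order(d$cluster)
  d$y <- d$y[ord]; d$X <- d$X[ord, , drop = FALSE]
  d$cluster <- d$cluster[ord]
  sp <- split_by_size(d)
  X <- d$X; y <- d$y
  p <- ncol(X)
  n_clusters <- length(unique(d$cluster))
  cl_s <- d$cluster[sp$s_idx]
  cl_p <- d$cluster[sp$p1]

  # GLS solve for beta given working response z, weights w and variance s;
  # returns beta, (X'V^-1 X)^-1, the BLUPs and the REML log-likelihood.
  gls_solve <- function(z, w, s, want_reml = FALSE) {
    vs <- 1 / w[sp$s_idx] + s
    XtVX <- crossprod(X[sp$s_idx, , drop = FALSE] / vs,
                      X[sp$s_idx, , drop = FALSE])
    XtVz <- crossprod(X[sp$s_idx, , drop = FALSE] / vs, z[sp$s_idx])
    logdet <- sum(log(vs))
    if (length(sp$p1)) {
      d1 <- 1 / w[sp$p1] + s
      d2 <- 1 / w[sp$p2] + s
      det2 <- d1 * d2 - s^2
      v11 <- d2 / det2; v12 <- -s / det2; v22 <- d1 / det2
      x1 <- X[sp$p1, , drop = FALSE]; x2 <- X[sp$p2, , drop = FALSE]
      z1 <- z[sp$p1]; z2 <- z[sp$p2]
      XtVX <- XtVX + crossprod(x1 * v11, x1) + crossprod(x1 * v12, x2) +
        crossprod(x2 * v12, x1) + crossprod(x2 * v22, x2)
      XtVz <- XtVz + crossprod(x1, v11 * z1 + v12 * z2) +
        crossprod(x2, v12 * z1 + v22 * z2)
      logdet <- logdet + sum(log(det2))
    }
    vc <- tryCatch(chol2inv(chol(XtVX)), error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    beta <- drop(vc %*% XtVz)
    r <- z - drop(X %*% beta)
    quad <- sum(r[sp$s_idx]^2 / vs)
    u <- rep(0, n_clusters)
    u[cl_s] <- s * r[sp$s_idx] / vs
    if (length(sp$p1)) {
      r1 <- r[sp$p1]; r2 <- r[sp$p2]
      quad <- quad + sum(v11 * r1^2 + 2 * v12 * r1 * r2 + v22 * r2^2)
      u[cl_p] <- s * ((v11 + v12) * r1 + (v12 + v22) * r2)
    }
    reml <- if (want_reml)
      -0.5 * (logdet + determinant(XtVX, logarithm = TRUE)$modulus + quad)
    else NA_real_
    list(beta = beta, vcov = vc, u = u, reml = as.numeric(reml))
  }

  start <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- start$coefficients
  u <- rep(0, n_clusters)
  s <- if (is.null(fix_sigma2)) 0.5 else fix_sigma2
  converged <- FALSE
  boundary <- FALSE
  iter <- 0L
  sol <- NULL
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + u[d$cluster]
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    if (is.null(fix_sigma2)) {
      opt <- stats::optimize(function(ls) {
        sol <- gls_solve(z, w, exp(ls), want_reml = TRUE)
        if (is.null(sol)) return(1e10)
        -sol$reml
      }, interval = c(-12, 4), tol = 1e-8)
      s_new <- exp(opt$minimum)
      boundary <- opt$minimum < -11.5
      if (boundary) s_new <- 0
    } else s_new <- fix_sigma2
    sol_new <- gls_solve(z, w, s_new)
    if (is.null(sol_new)) break
    sol <- sol_new
    delta <- max(abs(c(sol$beta - beta, s_new - s)))
    beta <- sol$beta; u <- sol$u; s <- s_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    if (any(!is.finite(beta)) || max(abs(beta)) > 1e8) break
  }
  if (is.null(sol)) {
    vc <- matrix(NA_real_, p, p)
    beta <- rep(NA_real_, p)
    s <- NA_real_
  } else {
    vc <- sol$vcov
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  notes <- if (boundary) "variance estimate at boundary 0" else character()
  new_cluster_fit("glmm_pql",
                  coefficients = stats::setNames(beta, colnames(X)),
                  se = stats::setNames(sqrt(pmax(diag(vc), 0)),
                                       colnames(X)),
                  vcov = vc, sigma2 = s, converged = converged,
                  n_iter = iter, diagnostics = notes,
                  n_obs = length(y), n_clusters = n_clusters)
}
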