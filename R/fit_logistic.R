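#' Maximum-likelihood logistic regression (clustering ignored)
#'
#' Ordinary logistic regression fitted by iteratively reweighted least
#' squares ([stats::glm.fit()]), with standard errors from the inverse
#' Fisher information. The clustering of twins is ignored entirely, so
#' standard errors are too small whenever outcomes are correlated within
#' pairs. Complete or quasi-complete separation (including a constant
#' outcome) is flagged as non-convergence.
#'
#' @param data Long-format data.frame with a binary outcome column.
#' @param covariates Character vector of covariate column names.
#' @param cluster_col,y_col Column names (cluster id is carried along for
#'   bookkeeping only).
#' @return A `cluster_fit` (see [cluster_logit()]).
#' @export
fit_logistic <- function(data, covariates, cluster_col = "cluster_id",
                         y_col = "y") {
  d <- prepare_design(data, covariates, cluster_col, y_col)
  fit <- suppressWarnings(
    stats::glm.fit(d$X, d$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8)
  w <- mu * (1 - mu)
  info <- crossprod(d$X * w, d$X)
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  diag_notes <- character()
  converged <- isTRUE(fit$converged) && !fit$boundary && !is.null(vc)
  if (separated) {
    converged <- FALSE
    diag_notes <- "complete or quasi-complete separation"
  }
  if (is.null(vc)) {
    vc <- matrix(NA_real_, ncol(d$X), ncol(d$X))
    diag_notes <- c(diag_notes, "singular information matrix")
  }
  dimnames(vc) <- list(colnames(d$X), colnames(d$X))
  se <- sqrt(pmax(diag(vc), 0))
  ll <- sum(d$y * log(pmax(mu, 1e-300)) +
              (1 - d$y) * log(pmax(1 - mu, 1e-300)))
  new_cluster_fit("logistic",
                  coefficients = stats::setNames(fit$coefficients,
                                                 colnames(d$X)),
                  se = stats::setNames(se, colnames(d$X)),
                  vcov = vc, converged = converged, n_iter = fit$iter,
                  loglik = ll, diagnostics = diag_notes,
                  n_obs = length(d$y),
                  n_clusters = length(unique(d$cluster)))
}
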