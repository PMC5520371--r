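# Shared fitting infrastructure: design preparation, the fit container,
# the divergence filter and the formula front-end.

# Validate a long-format dataset and build the design matrix.
# Clusters of size >= 3 are out of scope and rejected.
prepare_design <- function(data, covariates, cluster_col = "cluster_id",
                           y_col = "y") {
  if (!y_col %in% names(data)) stop("no outcome column '", y_col, "'")
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  y <- data[[y_col]]
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 with no missing values")
  cl <- if (cluster_col %in% names(data)) data[[cluster_col]] else
    seq_along(y)
  cl <- as.integer(factor(cl, levels = unique(cl)))
  sizes <- tabulate(cl)
  if (any(sizes > 2L))
    stop("clusters of size 3 or more are not supported")
  X <- cbind("(Intercept)" = 1,
             as.matrix(as.data.frame(data)[, covariates, drop = FALSE]))
  if (any(!is.finite(X))) stop("non-finite covariate values")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  list(y = as.numeric(y), X = X, cluster = cl, sizes = sizes)
}

# Split a prepared design into singleton rows and aligned pair rows.
split_by_size <- function(d) {
  first <- !duplicated(d$cluster)
  size_of_row <- d$sizes[d$cluster]
  s_idx <- which(size_of_row == 1L)
  p_first <- which(first & size_of_row == 2L)
  p_second <- p_first + 1L   # rows are cluster-contiguous after ordering
  ord <- order(d$cluster)
  if (is.unsorted(d$cluster)) {
    d$y <- d$y[ord]; d$X <- d$X[ord, , drop = FALSE]
    d$cluster <- d$cluster[ord]
    return(split_by_size(d))
  }
  list(s_idx = s_idx, p1 = p_first, p2 = p_second)
}

new_cluster_fit <- function(method, coefficients, se, vcov = NULL,
                            sigma2 = NA_real_, sigma2_se = NA_real_,
                            converged = TRUE, n_iter = NA_integer_,
                            loglik = NA_real_, diagnostics = character(),
                            n_obs = NA_integer_, n_clusters = NA_integer_,
                            extra = list()) {
  structure(c(list(method = method, coefficients = coefficients, se = se,
                   vcov = vcov, sigma2 = sigma2, sigma2_se = sigma2_se,
                   converged = converged, n_iter = n_iter, loglik = loglik,
                   diagnostics = diagnostics, n_obs = n_obs,
                   n_clusters = n_clusters), extra),
            class = "cluster_fit")
}

#' Discard fits with diverged parameter estimates
#'
#' Estimation routines occasionally return estimates of implausible
#' magnitude instead of failing. Following the study's bookkeeping rule,
#' a fit in which any coefficient exceeds the threshold in absolute value
#' (strictly) has all its estimates and standard errors replaced by `NA`
#' and is marked non-converged; estimates exactly at the threshold are
#' kept. The operation is idempotent.
#'
#' @param result A `cluster_fit` object.
#' @param threshold Divergence cut-off (default 1000).
#' @return The (possibly censored) `cluster_fit`.
#' @export
apply_divergence_filter <- function(result, threshold = 1000) {
  stopifnot(inherits(result, "cluster_fit"))
  est <- result$coefficients
  if (length(est) && any(abs(est) > threshold, na.rm = TRUE)) {
    result$coefficients[] <- NA_real_
    result$se[] <- NA_real_
    if (!is.null(result$vcov)) result$vcov[] <- NA_real_
    if (!is.na(result$sigma2)) result$sigma2 <- NA_real_
    result$converged <- FALSE
    result$diagnostics <- unique(c(result$diagnostics,
                                   "divergence filter triggered"))
  }
  result
}

#' Fit a regression model to clustered binary data
#'
#' Formula front-end to the four estimation procedures compared in the
#' package: ordinary maximum-likelihood logistic regression (`"logistic"`,
#' ignores clustering), the random-intercept logistic model estimated by
#' penalised quasi-likelihood (`"pql"`) or by adaptive Gauss-Hermite
#' quadrature (`"agq"`), and generalised estimating equations with an
#' exchangeable working correlation and robust sandwich standard errors
#' (`"gee"`). The mixed-model methods estimate cluster-specific
#' (conditional) effects; GEE estimates population-average (marginal)
#' effects, attenuated relative to the conditional ones.
#'
#' Only plain covariate columns are supported on the right-hand side of
#' the formula (the simulation study's models are all of this form).
#'
#' @param formula e.g. `y ~ bweight + sex`.
#' @param data Long-format data.frame, one row per infant.
#' @param cluster Name of the cluster id column (default `"cluster_id"`);
#'   clusters must have size 1 or 2.
#' @param method One of `"logistic"`, `"pql"`, `"agq"`, `"gee"`.
#' @param ... Passed to the underlying fitter ([fit_logistic()],
#'   [fit_glmm_pql()], [fit_glmm_agq()], [fit_gee_exchangeable()]).
#' @return An object of class `"cluster_fit"` with components
#'   `coefficients`, `se`, `vcov`, `sigma2` (mixed models only),
#'   `converged`, `n_iter`, `loglik` (likelihood-based methods) and
#'   `diagnostics`.
#' @examples
#' sc <- scenario(200, 0.1, ukos_outcome_spec("death", 2, sigma2 = 1),
#'                n_reps = 1)
#' d <- simulate_dataset(sc, 1)
#' fit <- cluster_logit(y ~ bweight + sex, d, method = "gee")
#' summary(fit)
#' @export
cluster_logit <- function(formula, data, cluster = "cluster_id",
                          method = c("logistic", "pql", "agq", "gee"),
                          ...) {
  method <- match.arg(method)
  tf <- stats::terms(formula, data = data)
  if (attr(tf, "response") != 1L) stop("formula needs a response")
  y_col <- as.character(attr(tf, "variables")[[2L]])
  covars <- attr(tf, "term.labels")
  if (!all(covars %in% names(data)))
    stop("only plain covariate column names are supported in the formula")
  fitter <- switch(method,
                   logistic = fit_logistic,
                   pql = fit_glmm_pql,
                   agq = fit_glmm_agq,
                   gee = fit_gee_exchangeable)
  fit <- fitter(data, covars, cluster_col = cluster, y_col = y_col, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.cluster_fit <- function(x, digits = 4, ...) {
  labels <- c(logistic = "Logistic regression (ML)",
              glmm_pql = "Random-intercept logistic (PQL)",
              glmm_agq = "Random-intercept logistic (adaptive Gauss-Hermite)",
              gee = "GEE, exchangeable working correlation")
  cat(labels[[x$method]], "\n")
  if (!x$converged) cat("** did not converge **\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (!is.na(x$sigma2))
    cat("Random-intercept variance:", format(x$sigma2, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.cluster_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.cluster_fit")
}

#' @export
print.summary.cluster_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.na(x$fit$loglik))
    cat("log-likelihood:", format(x$fit$loglik), "\n")
  if (length(x$fit$diagnostics))
    cat("diagnostics:", paste(x$fit$diagnostics, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.cluster_fit <- function(object, ...) object$coefficients

#' @export
vcov.cluster_fit <- function(object, ...) object$vcov

#' @export
confint.cluster_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - q * object$se,
              object$coefficients + q * object$se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.cluster_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              as.integer(!is.na(object$sigma2)), class = "logLik")
}
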