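# Monte-Carlo comparison metrics over replicate fit collections.
# All metrics are computed over the converged fits only; sample variances
# use the n-1 denominator throughout.

#' Relative bias of replicate estimates
#'
#' Mean over replicates of `(estimate - beta_true) / beta_true`; positive
#' values mean the parameter is overestimated on average, negative values
#' attenuation toward zero (for a negative true coefficient an estimate
#' closer to zero than the truth gives a negative relative bias).
#'
#' @param estimates Numeric vector of converged replicate estimates.
#' @param beta_true True (generating) coefficient, non-zero.
#' @return Dimensionless mean relative bias.
#' @export
relative_bias <- function(estimates, beta_true) {
  if (!length(estimates)) stop("no estimates supplied")
  if (beta_true == 0) stop("relative bias is undefined for beta_true = 0")
  mean((estimates - beta_true) / beta_true)
}

#' Conditional-to-marginal coefficient conversion
#'
#' GEE estimates population-average effects, which are attenuated relative
#' to the cluster-specific effects of the generating random-intercept
#' model. The standard logit approximation gives
#' \deqn{\beta_{GEE} = \sqrt{1 / (0.346\,\sigma^2_{u_0} + 1)}\;\beta,}
#' and this converted value is used as the truth when computing bias,
#' coverage and MSE for GEE. (Logistic regression, though also marginal in
#' flavour, is judged against the conditional coefficient without
#' conversion, matching how its output is read in practice.)
#'
#' @param beta_conditional Conditional (cluster-specific) coefficient.
#' @param sigma2_true True random-intercept variance, `>= 0`.
#' @return The approximate marginal coefficient.
#' @examples
#' convert_to_marginal(-0.004, 2)  # -0.003076
#' @export
convert_to_marginal <- function(beta_conditional, sigma2_true) {
  if (any(sigma2_true < 0)) stop("'sigma2_true' must be non-negative")
  beta_conditional * sqrt(1 / (0.346 * sigma2_true + 1))
}

#' Empirical bias with a 95% confidence interval
#'
#' `mean(estimates) - beta_true`, with a normal-approximation interval
#' `bias +/- 1.96 * sd(estimates) / sqrt(n)` for the Monte-Carlo mean.
#'
#' @inheritParams relative_bias
#' @return Named vector `c(bias, ci_low, ci_high)`.
#' @export
empirical_bias_ci <- function(estimates, beta_true) {
  n <- length(estimates)
  if (n < 2L) stop("need at least 2 estimates")
  bias <- mean(estimates) - beta_true
  half <- 1.96 * stats::sd(estimates) / sqrt(n)
  c(bias = bias, ci_low = bias - half, ci_high = bias + half)
}

#' Coverage of the 95% Wald interval
#'
#' Fraction of replicates whose interval `estimate +/- 1.96 * se` contains
#' the true value (for GEE the converted marginal truth).
#'
#' @param estimates,ses Equal-length vectors from converged fits.
#' @inheritParams relative_bias
#' @return A proportion in `[0, 1]`.
#' @export
coverage_95 <- function(estimates, ses, beta_true) {
  if (length(estimates) != length(ses))
    stop("'estimates' and 'ses' must have equal length")
  mean(estimates - 1.96 * ses <= beta_true &
         beta_true <= estimates + 1.96 * ses)
}

#' Mean squared error of replicate estimates
#'
#' `MSE = var(estimates) + (mean(estimates) - beta_true)^2`, with the
#' sample variance on the `n - 1` denominator.
#'
#' @inheritParams relative_bias
#' @return MSE in squared coefficient units.
#' @export
mean_squared_error <- function(estimates, beta_true) {
  if (length(estimates) < 2L) stop("need at least 2 estimates")
  stats::var(estimates) + (mean(estimates) - beta_true)^2
}

#' Percentage of non-converged fits
#'
#' Computed after the divergence filter, so filter-triggered fits count as
#' non-converged.
#'
#' @param results List of `cluster_fit` objects (or logical convergence
#'   flags).
#' @return Percentage in `[0, 100]`.
#' @export
nonconvergence_rate <- function(results) {
  if (!length(results)) stop("empty result list")
  flags <- vapply(results, function(r)
    if (is.logical(r)) r else isTRUE(r$converged), logical(1))
  100 * mean(!flags)
}

#' Summarise one scenario's replicate fits
#'
#' Computes, per method and per reported parameter, the full metric set of
#' the study: relative bias, empirical bias with its 95% CI, coverage of
#' the 95% Wald interval, MSE, the non-convergence percentage and (for the
#' mixed-model methods) the mean and SD of the random-intercept variance
#' estimates over converged fits. The truth is the conditional generating
#' coefficient for logistic/PQL/AGQ and the converted marginal coefficient
#' ([convert_to_marginal()] at the scenario's true variance) for GEE.
#'
#' @param results Named list: method name -> list of `cluster_fit`s (one
#'   per replicate, divergence filter already applied).
#' @param scenario The generating [scenario()].
#' @param parameters Coefficients to report (default: all generating
#'   coefficients).
#' @return A data.frame with one row per (method, parameter).
#' @export
summarize_scenario <- function(results, scenario,
                               parameters = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  beta_true <- scenario$outcome_spec$coefficients
  sigma2 <- scenario$outcome_spec$sigma2
  if (is.null(parameters)) parameters <- names(beta_true)
  out <- list()
  for (method in names(results)) {
    fits <- results[[method]]
    if (!length(fits))
      stop("no fits supplied for method '", method, "'")
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    nonconv <- 100 * mean(!conv)
    fits_c <- fits[conv]
    is_glmm <- length(fits_c) > 0 &&
      !is.na(fits_c[[1L]]$sigma2)
    v_mean <- v_sd <- NA_real_
    if (is_glmm) {
      v <- vapply(fits_c, function(f) f$sigma2, numeric(1))
      v_mean <- mean(v)
      v_sd <- if (length(v) > 1L) stats::sd(v) else NA_real_
    }
    for (par in parameters) {
      truth <- beta_true[[par]]
      target <- if (identical(method, "gee"))
        convert_to_marginal(truth, sigma2) else truth
      est <- vapply(fits_c, function(f) f$coefficients[[par]], numeric(1))
      se <- vapply(fits_c, function(f) f$se[[par]], numeric(1))
      if (length(est) >= 2L) {
        bci <- empirical_bias_ci(est, target)
        row <- data.frame(
          scenario = scenario$id, method = method, parameter = par,
          beta_true = truth, beta_target = target,
          rel_bias = if (target != 0) relative_bias(est, target) else
            NA_real_,
          emp_bias = bci[["bias"]], ci_lo = bci[["ci_low"]],
          ci_hi = bci[["ci_high"]],
          coverage = coverage_95(est, se, target),
          mse = mean_squared_error(est, target),
          nonconv_pct = nonconv, var_mean = v_mean, var_sd = v_sd,
          n_converged = length(est), stringsAsFactors = FALSE)
      } else {
        row <- data.frame(
          scenario = scenario$id, method = method, parameter = par,
          beta_true = truth, beta_target = target, rel_bias = NA_real_,
          emp_bias = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          coverage = NA_real_, mse = NA_real_, nonconv_pct = nonconv,
          var_mean = v_mean, var_sd = v_sd, n_converged = length(est),
          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write scenario summaries as CSV
#'
#' One row per (scenario, method, parameter); the empirical bias and its
#' interval are additionally exported on the x 10^4 scale used for the
#' printed bias tables (`emp_bias_1e4`, `ci_lo_1e4`, `ci_hi_1e4`).
#'
#' @param summaries Data.frame from [summarize_scenario()] (possibly
#'   row-bound over scenarios).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  summaries$emp_bias_1e4 <- summaries$emp_bias * 1e4
  summaries$ci_lo_1e4 <- summaries$ci_lo * 1e4
  summaries$ci_hi_1e4 <- summaries$ci_hi * 1e4
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
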