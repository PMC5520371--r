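#' Outcome-generating model specification
#'
#' Bundles the ingredients of the two-level logit model used to generate a
#' binary outcome: an intercept and regression coefficients on the logit
#' scale (per gram for birthweight, per week for gestational age, per unit
#' for Apgar, indicator contrasts for sex and smoking) and the
#' random-intercept variance \eqn{\sigma^2_{u_0}} (logit^2 units) shared by
#' both members of a cluster.
#'
#' @param outcome_name Label for the outcome (e.g. `"death"`, `"o2dep"`).
#' @param coefficients Named numeric vector; must contain `"(Intercept)"`,
#'   the remaining names are covariate labels.
#' @param sigma2 Random-intercept variance, `>= 0`.
#' @return An object of class `"outcome_spec"`.
#' @export
outcome_spec <- function(outcome_name, coefficients, sigma2 = 0) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("'coefficients' must be a fully named numeric vector")
  if (!"(Intercept)" %in% names(coefficients))
    stop("'coefficients' must contain an \"(Intercept)\" entry")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) ||
      sigma2 < 0)
    stop("'sigma2' must be a single non-negative number")
  structure(list(outcome_name = outcome_name,
                 coefficients = coefficients,
                 sigma2 = sigma2),
            class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat("Outcome model:", x$outcome_name, "\n")
  print(round(x$coefficients, 4))
  cat("random-intercept variance:", x$sigma2, "\n")
  invisible(x)
}

# Coefficients estimated from the source preterm-infant cohort with the
# adaptive Gauss-Hermite random-intercept model; these are the "true"
# generating parameters of the simulation scenarios.
ukos_coefficients <- list(
  death = list(
    `4` = c("(Intercept)" = 10.70, bweight = -0.004, sex = 0.410,
            gestage = -0.039, apgar = -0.212),
    `2` = c("(Intercept)" = 3.037, bweight = -0.006, sex = 0.598)),
  o2dep = list(
    `4` = c("(Intercept)" = 14.7, bweight = -0.0045, sex = 0.954,
            gestage = -0.058, smoking = 0.654),
    `2` = c("(Intercept)" = 5.315, bweight = -0.006, sex = 1.001)))

# Observed marginal prevalences of the two outcomes in the source cohort;
# intercept calibration targets for the synthetic covariate model.
ukos_prevalence <- c(death = 0.26, o2dep = 0.56)

#' Outcome specifications of the preterm-infant simulation study
#'
#' Returns the generating regression coefficients for one of the four
#' outcome / covariate-count combinations: death before discharge or oxygen
#' dependence at 36 weeks postmenstrual age, each with either two
#' covariates (birthweight, sex) or four (plus gestational age and Apgar
#' for death, gestational age and smoking for oxygen dependence). The
#' random-intercept variance is a scenario parameter, not a property of the
#' coefficient set, so it must be supplied.
#'
#' The cohort's observed marginal prevalence (26% death, 56% oxygen
#' dependence) is attached as attribute `"target_prevalence"`; because the
#' packaged covariate model is synthetic, [calibrate_intercept()] should be
#' used to re-anchor the intercept to that prevalence before simulating.
#'
#' @param outcome `"death"` or `"o2dep"`.
#' @param n_covariates 2 or 4.
#' @param sigma2 Random-intercept variance for the scenario (default 0).
#' @return An [outcome_spec()] with attribute `"target_prevalence"`.
#' @export
ukos_outcome_spec <- function(outcome = c("death", "o2dep"),
                              n_covariates = 4, sigma2 = 0) {
  outcome <- match.arg(outcome)
  n_covariates <- as.character(n_covariates)
  if (!n_covariates %in% c("2", "4"))
    stop("'n_covariates' must be 2 or 4")
  spec <- outcome_spec(outcome,
                       ukos_coefficients[[outcome]][[n_covariates]],
                       sigma2 = sigma2)
  attr(spec, "target_prevalence") <- unname(ukos_prevalence[outcome])
  spec
}
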