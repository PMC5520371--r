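---
title: "Comparing methods for binary outcomes when a few clusters have size two"
author: "twinsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing methods for binary outcomes when a few clusters have size two}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinsim)
```

## The problem

Cohorts of preterm infants are mostly made of singleton births, but a
non-negligible fraction of infants (often 10--30%) come from multiple
births. Outcomes of twins are correlated -- they share gestational age,
maternal factors and much of their care -- so a dataset of such infants is
a clustered dataset of an unusual shape: almost all clusters have size
one, a few have size two. Standard advice for clustered data (mixed
models, GEE) was developed for many observations per cluster; very little
of it tells an analyst what happens when the within-cluster information is
this thin. `twinsim` is a Monte-Carlo laboratory for exactly that
question, for binary outcomes such as death before discharge or oxygen
dependence at 36 weeks postmenstrual age.

## The data-generating model

A replicate dataset is built in six steps:

1. Given `n_clusters` and a twin fraction, the number of twin-pair
   clusters is `round(twin_fraction * n_clusters)` (half away from zero);
   the rest are singletons.
2. Each cluster draws one combination of categorical covariate levels
   (sex; maternal smoking where used) from a multinomial table -- one
   table for singletons, one for twin pairs. Both members of a pair share
   the combination, so twins here always share sex. Discordant-sex twin
   simulation is deliberately not attempted: the cluster-level draw is the
   simplest structure consistent with a per-cluster covariate model, and
   with effects of the size studied the difference is immaterial for the
   estimand comparisons.
3. Continuous covariates (birthweight in grams, gestational age in weeks,
   Apgar score) are drawn from a multivariate normal whose mean and
   covariance depend on (cluster kind, categorical profile). For a twin
   pair the draw is from the joint `2k`-dimensional normal over both
   siblings, so cross-sibling correlation is preserved.
4. Simulated Apgar values are folded back into the admissible range:
   values above 12 become 10, values in (10, 12] become 9, everything at
   or below 10 is kept (scores stay continuous).
5. Each cluster draws a random intercept `u ~ N(0, sigma2)`, shared by
   both twins.
6. The outcome of infant `j` in cluster `i` is Bernoulli with
   `logit(p_ij) = beta0 + u_i + beta' x_ij`.

The regression coefficients are the ones estimated from the source cohort
(death and oxygen dependence, each with a 2- and a 4-covariate version);
the random-intercept variance is a scenario parameter with grid values
0.5, 1 and 2 (optionally 4 and 8), the twin percentage runs from 2 to
20%, and the number of clusters is 150, 500 or 1000. The full study uses
5000 replicates per scenario.

## The packaged covariate model is synthetic

The original cohort's covariate distribution parameters (per-profile
means and covariance matrices) are not publicly deposited. The packaged
model (`ukos_covariate_model()`, also shipped as
`inst/extdata/ukos_synthetic_covariates.json`) is therefore an explicitly
synthetic stand-in with realistic extremely-preterm ranges: birthweight
around 750 g (SD 160 g), gestational age around 26 weeks (SD 1.5 w),
Apgar around 6 (SD 2), twins about 65 g lighter and half a week earlier.
Cross-sibling dependence uses a shared/individual variance decomposition
(which keeps the joint 6x6 covariance positive definite by construction):
within-pair correlations are 0.70 for birthweight, 0.99 for gestational
age -- effectively identical within a pair while avoiding a singular
covariance -- and 0.30 for Apgar.

Because the covariates are a stand-in, the printed intercepts do not
reproduce the cohort's outcome prevalences under them.
`calibrate_intercept()` re-anchors the intercept so that the simulated
marginal prevalence matches the observed 26% (death) or 56% (oxygen
dependence): it freezes one large Monte-Carlo draw of covariates and
cluster effects (default 200,000 infants), which makes the prevalence a
smooth, strictly increasing, deterministic function of the intercept, and
solves for the root by bisection. All slope coefficients are left
untouched. Scenario runs use the calibrated intercept by default
(`run_grid(..., calibrate = TRUE)`).

What passing tests on this generator do show: correctness of the
estimators and metrics, and the qualitative mechanics of the design
(attenuation with increasing variance, information about `sigma2` scaling
with the number of pairs). What they cannot show: agreement with any
number that depends on the original covariate distribution itself.

## The four estimators

All four are fitted to the same replicate dataset:

* **Logistic regression** (`fit_logistic()`): ordinary maximum likelihood
  via IRLS, clustering ignored. Complete or quasi-complete separation
  (including a constant outcome) is recorded as non-convergence.
* **Random-intercept logistic, PQL** (`fit_glmm_pql()`): the classic
  penalised quasi-likelihood loop -- working response
  `z = eta + (y - p)/w`, `w = p(1 - p)`, a weighted mixed-model solve for
  the fixed effects and cluster intercepts, and a REML update of `sigma2`
  on the working linear model with the conditional variance `1/w` treated
  as known (binomial dispersion fixed at 1; `MASS::glmmPQL`, by contrast,
  also estimates a dispersion, which is the main reason the two give
  slightly different numbers). Outer iteration stops when no parameter
  moves by more than 1e-6; cap 50 iterations.
* **Random-intercept logistic, adaptive Gauss--Hermite**
  (`fit_glmm_agq()`): maximises the exact marginal likelihood, each
  cluster integral approximated by a Gauss--Hermite rule recentred at the
  cluster's posterior mode and rescaled by the curvature there. Five
  nodes per axis is the study setting; with clusters of size at most two
  this gives the log-likelihood to about 1e-4 relative accuracy, and the
  same machinery converges to brute-force integration as nodes increase
  (about 6e-7 at 11 nodes, 4e-8 at 15 -- the test suite verifies the
  1e-6 regime at 15 nodes). One node gives the Laplace approximation.
  The outer optimisation is quasi-Newton over `(beta, log sigma)` with
  `log sigma` bounded below at -10; a fit ending on that bound is
  reported as `sigma2 = 0` with a boundary diagnostic, not as a failure.
  Covariates are standardised internally (birthweight in grams next to
  0/1 indicators makes the raw problem badly conditioned) and estimates
  mapped back. Optimiser exits that report a flat ("singular/false
  convergence") surface are accepted only after an explicit gradient
  check; standard errors come from the numerically differentiated
  observed information, with the `sigma2` interval formed on the log
  scale.
* **GEE, exchangeable working correlation** (`fit_gee_exchangeable()`):
  Fisher scoring on the estimating equations with logit link. The working
  correlation is a moment estimator from cross-products of standardised
  Pearson residuals over the twin pairs; singletons carry no information
  about it. No degrees-of-freedom correction is applied in its
  denominator -- with 3 pairs and 5 parameters the usual `n_pairs - p`
  denominator is non-positive -- and the estimate is clamped to
  |rho| <= 0.95 (with a boundary diagnostic) because a moment estimate
  from a handful of pairs regularly leaves the valid range and a
  near-singular working covariance otherwise sends the update to
  astronomically large coefficients. Standard errors are robust sandwich
  estimates without small-sample correction.

Fits whose coefficients still exceed 1000 in absolute value (strictly)
are censored by `apply_divergence_filter()`: all estimates become `NA`
and the fit counts as non-converged. This mirrors how diverged fits
(magnitudes around 1e12 were observed) are bookkept in the study design;
the cut-point is arbitrary by construction since diverged estimates are
either small or enormous.

## Conditional versus marginal truth

The mixed models estimate cluster-specific (conditional) effects; GEE
estimates population-average (marginal) effects, attenuated by
approximately `sqrt(1/(0.346 * sigma2 + 1))`. The evaluation layer
therefore judges GEE against the converted truth
(`convert_to_marginal()`) and the other three methods against the
generating conditional coefficients -- including plain logistic
regression, deliberately without conversion, because that is how its
output is read in practice. The 0.346 rule is an approximation: on a
single binary covariate with `sigma2 = 2` it is about 6% away from the
exactly integrated marginal log-odds ratio (the test suite computes
both); under the packaged covariate model, where the linear predictor is
dominated by a continuous covariate, it agrees with the large-sample GEE
estimand to well within Monte-Carlo resolution.

## Evaluation metrics

Per scenario, method and parameter, over converged fits only: relative
bias `mean((est - beta)/beta)`; empirical bias `mean(est) - beta` with
the normal-approximation interval `bias +/- 1.96 sd/sqrt(n)` (the CI
method is a package choice; it is the standard one for Monte-Carlo means
of this size); coverage of `est +/- 1.96 se`; MSE as sample variance
(denominator `n - 1`, a documented convention choice) plus squared bias;
the non-convergence percentage after the divergence filter; and, for the
mixed models, the mean and SD of `sigma2` estimates. Because metrics are
computed per method over that method's converged subset, denominators may
differ across methods within a scenario.

## Reproducibility and problem sizes

Every replicate's seed is a deterministic 31-bit hash of (master seed,
scenario id, replicate index) (`replicate_seed()`), so a replicate can be
regenerated in isolation and results are identical whether a scenario is
run serially or with forked workers; the reducer collects in replicate
index order regardless of completion order.

The packaged test and acceptance runs use reduced problem sizes chosen to
keep the full pattern checks to a few minutes while leaving Monte-Carlo
error well below the effects being asserted: pattern reproduction uses
500 replicates of 150-cluster scenarios (the study's smallest sample
size, where the patterns are strongest), parameter recovery uses 100
replicates of 2000 twin pairs, and the prevalence checks use about
200,000 simulated infants. The headline bias quantity is recomputed at
the study's full 5000 replicates, which a few minutes of GEE fitting
covers.

## Known limitations

* The covariate model is synthetic; nothing here reproduces numbers that
  depend on the original cohort's covariate distribution.
* Clusters of size three or more (higher-order multiples), informative
  cluster size, and hospital-level clustering are out of scope; the
  fitters reject clusters of size >= 3.
* On singleton-only (or nearly so) data the GLMM likelihood is almost
  flat along the ridge `(beta scaled by the attenuation factor, sigma2)`;
  any correct maximiser (this one and `lme4::glmer` alike) may return a
  positive `sigma2` with a correspondingly inflated conditional slope
  while the implied population-average slope is stable. Comparisons on
  such data should be made on the marginal scale.
* Exact replication of any particular software's non-convergence
  percentages is not attempted: they are optimizer-implementation
  artefacts, and the stabilisations described above deliberately make
  this GEE implementation fail less often than the reference study's.
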