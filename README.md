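# twinsim

Datasets of preterm infants are mostly independent observations
(singleton births) plus a small fraction of clusters of size two — twin
pairs whose outcomes are correlated. When a binary outcome such as death
before discharge or oxygen dependence at 36 weeks is analysed in such
data, the analyst has to pick between ignoring the clustering (ordinary
logistic regression), a random-intercept logistic model (estimated by
penalised quasi-likelihood or adaptive Gauss–Hermite quadrature), or
generalised estimating equations. `twinsim` is a Monte-Carlo laboratory
for comparing those choices under realistic conditions: a synthetic-data
generator that mimics a preterm cohort, the four estimators behind one
fitting front-end, and an evaluation layer that measures bias, coverage,
mean squared error and non-convergence over a scenario grid.

## The model

Outcomes are generated from a two-level logistic model: for infant `j`
in cluster `i`,

    logit(p_ij) = β0 + u_i + β1·BW_ij + β2·SEX_ij + …,
    u_i ~ N(0, σ²_u0),

with clusters of size one or two, the random intercept shared by both
twins of a pair, and covariates (birthweight, sex, gestational age,
Apgar, maternal smoking) drawn from stratified multivariate normals —
jointly over both siblings for a pair, so birthweight correlates 0.70
within pairs. The mixed models estimate the conditional (cluster-specific)
β; GEE estimates the population-average β, attenuated by approximately
`sqrt(1/(0.346·σ²_u0 + 1))`, and is judged against that converted target.

## A worked example

```r
library(twinsim)

# a scenario: 150 clusters, 10% twin pairs, death model with 2 covariates,
# random-intercept variance 1, intercept calibrated so the simulated
# prevalence matches the cohort's 26%
spec <- calibrated_outcome_spec("death", 2, sigma2 = 1, seed = 1)
sc   <- scenario(150, 0.10, spec, n_reps = 200, master_seed = 1)
d    <- simulate_dataset(sc, 1)

fit <- cluster_logit(y ~ bweight + sex, d, method = "agq")
fit
#> Random-intercept logistic (adaptive Gauss-Hermite)
#> Coefficients:
#> (Intercept)     bweight         sex
#>      1.7343     -0.0052      1.5498
#> Random-intercept variance: 0.626

res <- run_scenario(sc, methods = c("logistic", "agq", "gee"))
subset(res$summary, parameter == "bweight",
       select = c(method, rel_bias, coverage, mse, nonconv_pct))
#>     method     rel_bias coverage          mse nonconv_pct
#> 2 logistic -0.128695503    0.910 2.092560e-06           0
#> 5      agq  0.083469121    0.965 4.786103e-06           0
#> 8      gee  0.004768346    0.970 1.467583e-06           0
```

Read: over 200 replicates of this scenario the logistic slope for
birthweight is attenuated toward zero by about 13% (negative relative
bias of a negative coefficient) and its 95% interval under-covers; the
adaptive-quadrature mixed model removes the attenuation (at the price of
a larger variance in this small sample), and GEE — measured against its
own marginal target — is essentially unbiased with the smallest mean
squared error.
`run_grid()` runs the full scenario grid (sample sizes × twin
percentages × variances × outcomes × covariate counts) with per-replicate
seed substreams, and `render_tables()` pivots the summaries into
bias/coverage/MSE/variance tables.

Because the original cohort's covariate distribution parameters are not
publicly available, the packaged covariate model is an explicitly
synthetic stand-in (see `?ukos_covariate_model` and the vignette); the
intercepts are re-calibrated at run time to the cohort's printed outcome
prevalences (26% and 56%).

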