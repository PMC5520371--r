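Package: twinsim
Title: Simulation-Based Comparison of Methods for Binary Outcomes in
    Datasets with a Small Fraction of Twin Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how standard regression methods behave when a
    binary outcome is analysed in a dataset formed mostly of independent
    observations (singleton births) plus a small fraction of clusters of
    size two (twin pairs). Provides a synthetic-data generator that mimics
    a preterm-infant cohort (stratified multivariate-normal covariates,
    random-intercept logit outcome), four estimation procedures (maximum
    likelihood logistic regression, random-intercept logistic regression by
    penalised quasi-likelihood and by adaptive Gauss-Hermite quadrature,
    and generalised estimating equations with exchangeable working
    correlation and robust standard errors), a divergence filter for
    unstable fits, and a Monte-Carlo evaluation layer computing relative
    bias, empirical bias with confidence intervals, coverage of the 95%
    Wald interval, mean squared error and non-convergence rates over a
    scenario grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    lme4,
    MASS,
    nlme,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
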