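test_that("logistic fit reproduces the closed-form 2x2 solution", {
  d <- data.frame(cluster_id = 1:40, member = 1L,
                  x = rep(c(0, 1), each = 20),
                  y = c(rep(1, 10), rep(0, 10), rep(1, 15), rep(0, 5)))
  f <- fit_logistic(d, "x")
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), c(0, log(3)), tolerance = 1e-6)
  expect_equal(unname(f$se[2]), sqrt(1 / 10 + 1 / 10 + 1 / 15 + 1 / 5),
               tolerance = 1e-6)
})

test_that("constant outcome and separation are flagged as non-convergence", {
  d <- data.frame(cluster_id = 1:20, member = 1L, x = rnorm(20), y = 0)
  f <- fit_logistic(d, "x")
  expect_false(f$converged)
  d2 <- data.frame(cluster_id = 1:20, member = 1L,
                   x = c(rep(0, 10), rep(1, 10)),
                   y = c(rep(0, 10), rep(1, 10)))
  expect_false(fit_logistic(d2, "x")$converged)
})

test_that("a null covariate effect is estimated near zero", {
  set.seed(31)
  d <- make_iid_logistic(20000, beta0 = -0.3, beta1 = 0)
  f <- fit_logistic(d, "x")
  expect_lt(abs(f$coefficients[["x"]]), 3 * f$se[["x"]])
})

test_that("GEE on singleton-only data equals logistic with HC0 sandwich SEs", {
  set.seed(32)
  d <- make_iid_logistic(800)
  fg <- fit_gee_exchangeable(d, "x")
  fl <- fit_logistic(d, "x")
  expect_true(fg$converged)
  expect_equal(fg$coefficients, fl$coefficients, tolerance = 1e-6)
  expect_match(fg$diagnostics, "no clusters of size 2")
  g0 <- stats::glm(y ~ x, stats::binomial(), d)
  hc0 <- sqrt(diag(sandwich::vcovHC(g0, type = "HC0")))
  expect_equal(unname(fg$se), unname(hc0), tolerance = 1e-5)
})

test_that("duplicated twin pairs drive the working correlation to its boundary", {
  set.seed(33)
  base <- make_iid_logistic(300)
  dup <- base[rep(seq_len(300), each = 2), ]
  dup$member <- rep(1:2, 300)
  fg <- fit_gee_exchangeable(dup, "x")
  expect_match(fg$diagnostics, "boundary")
  expect_gt(fg$rho, 0.9)
  # point estimates equal the logistic fit on one member per pair
  fl <- fit_logistic(base, "x")
  expect_equal(fg$coefficients, fl$coefficients, tolerance = 1e-6)
})

test_that("GEE estimates the attenuated marginal slope", {
  set.seed(34)
  est <- replicate(30, {
    d <- make_twin_pairs(2000, beta0 = -0.3, beta1 = 0.8, sigma2 = 2)
    fit_gee_exchangeable(d, "x")$coefficients[["x"]]
  })
  # exact marginal log-odds ratio by integrating over the random effect
  p0 <- stats::integrate(function(u)
    stats::plogis(-0.3 + u) * stats::dnorm(u, 0, sqrt(2)), -20, 20)$value
  p1 <- stats::integrate(function(u)
    stats::plogis(0.5 + u) * stats::dnorm(u, 0, sqrt(2)), -20, 20)$value
  exact <- stats::qlogis(p1) - stats::qlogis(p0)
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - exact), 3 * mc_se)
  # the sqrt(1/(0.346 sigma2 + 1)) rule approximates that attenuation
  expect_equal(exact / 0.8, convert_to_marginal(1, 2), tolerance = 0.1)
})

test_that("divergence filter censors only strictly over-threshold fits", {
  ok <- stub_fit(c("(Intercept)" = 0.2, x = -1.5), c(0.1, 0.1))
  expect_identical(apply_divergence_filter(ok), ok)
  edge <- stub_fit(c("(Intercept)" = 1000, x = 0), c(1, 1))
  expect_true(apply_divergence_filter(edge)$converged)
  bad <- stub_fit(c("(Intercept)" = 1e12, x = 0.5), c(1, 1))
  out <- apply_divergence_filter(bad)
  expect_false(out$converged)
  expect_true(all(is.na(out$coefficients)))
  expect_true(all(is.na(out$se)))
  expect_identical(apply_divergence_filter(out), out)  # idempotent
})

test_that("PQL with the variance held at zero degenerates to logistic regression", {
  set.seed(35)
  d <- make_twin_pairs(300, sigma2 = 1)
  fp <- fit_glmm_pql(d, "x", fix_sigma2 = 0)
  fl <- fit_logistic(d, "x")
  expect_equal(fp$coefficients, fl$coefficients, tolerance = 1e-6)
})

test_that("PQL cannot identify a random effect from singleton-only data", {
  set.seed(36)
  d <- make_iid_logistic(400)
  fp <- fit_glmm_pql(d, "x")
  fl <- fit_logistic(d, "x")
  # with one observation per cluster the variance component is not
  # identified; the REML update keeps it near zero and the fixed effects
  # track the plain logistic fit
  expect_lt(fp$sigma2, 0.1)
  expect_equal(fp$coefficients, fl$coefficients, tolerance = 0.01)
})

test_that("PQL tracks the reference implementation on well-behaved paired data", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("nlme")
  set.seed(37)
  d <- make_twin_pairs(1000, beta0 = -0.5, beta1 = 0.8, sigma2 = 1)
  fp <- fit_glmm_pql(d, "x")
  ref <- suppressMessages(MASS::glmmPQL(y ~ x, random = ~1 | cluster_id,
                                        family = stats::binomial(),
                                        data = d, verbose = FALSE))
  expect_equal(unname(fp$coefficients), unname(nlme::fixef(ref)),
               tolerance = 0.1)
  expect_equal(unname(fp$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 0.1)
  # both PQL routes shrink the variance component on binary pair data
  expect_lt(fp$sigma2, 1)
})

test_that("AGQ marginal likelihood matches brute-force integration", {
  set.seed(38)
  d <- data.frame(cluster_id = rep(1:4, each = 2),
                  member = rep(1:2, 4),
                  x = rnorm(8))
  d$y <- rbinom(8, 1, plogis(-0.4 + 0.6 * d$x))
  beta <- c(-0.4, 0.6)
  ll_brute <- brute_marginal_loglik(d, beta, 1, "x")
  prep <- twinsim:::prepare_design(d, "x")
  sp <- twinsim:::split_by_size(prep)
  eta <- drop(prep$X %*% beta)
  ll_agq <- twinsim:::agq_loglik(eta[sp$p1], eta[sp$p2],
                                 prep$y[sp$p1], prep$y[sp$p2],
                                 rep(1, length(sp$p1)), 1,
                                 gauss_hermite_rule(15))$loglik
  expect_equal(ll_agq, ll_brute, tolerance = 1e-6 * abs(ll_brute))
})

test_that("AGQ with sigma2 fixed at zero equals logistic regression", {
  set.seed(39)
  d <- make_twin_pairs(200, sigma2 = 0.5)
  fa <- fit_glmm_agq(d, "x", fix_sigma2 = 0)
  fl <- fit_logistic(d, "x")
  expect_equal(fa$coefficients, fl$coefficients, tolerance = 1e-6)
})

test_that("AGQ agrees with lme4::glmer at five quadrature points", {
  skip_if_not_installed("lme4")
  set.seed(40)
  d <- make_twin_pairs(600, beta0 = -0.5, beta1 = 0.8, sigma2 = 1)
  fa <- fit_glmm_agq(d, "x")
  ref <- suppressWarnings(
    lme4::glmer(y ~ x + (1 | cluster_id), data = d,
                family = stats::binomial(), nAGQ = 5))
  expect_equal(unname(fa$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(fa$sigma2, unname(unlist(lme4::VarCorr(ref))),
               tolerance = 1e-2)
  expect_equal(unname(fa$se), unname(sqrt(diag(as.matrix(stats::vcov(ref))))),
               tolerance = 0.02)
})

test_that("the maximized AGQ log-likelihood nests the logistic one", {
  set.seed(41)
  for (i in 1:5) {
    d <- make_twin_pairs(150, sigma2 = runif(1, 0, 1.5))
    fa <- fit_glmm_agq(d, "x")
    fl <- fit_logistic(d, "x")
    if (fa$converged && fl$converged)
      expect_gte(fa$loglik, fl$loglik - 1e-6)
  }
})

test_that("PQL underestimates the variance component relative to AGQ", {
  set.seed(42)
  diffs <- replicate(15, {
    d <- make_twin_pairs(400, sigma2 = 1)
    fit_glmm_pql(d, "x")$sigma2 - fit_glmm_agq(d, "x")$sigma2
  })
  expect_lt(mean(diffs), 0)
})

test_that("all methods agree on large independent data", {
  set.seed(43)
  d <- make_iid_logistic(20000)
  fits <- list(fit_logistic(d, "x"), fit_glmm_pql(d, "x"),
               fit_glmm_agq(d, "x"), fit_gee_exchangeable(d, "x"))
  # on singleton-only data the GLMM likelihood is flat along the
  # (scaled slope, sigma2) ridge, so the AGQ slope is compared on the
  # population-average scale via its own attenuation factor
  slopes <- vapply(fits, function(f) {
    b <- f$coefficients[["x"]]
    if (!is.na(f$sigma2) && f$method == "glmm_agq")
      convert_to_marginal(b, f$sigma2) else b
  }, numeric(1))
  mc_se <- fits[[1]]$se[["x"]]
  expect_lt(max(slopes) - min(slopes), 3 * mc_se)
})

test_that("fits are deterministic and covariance estimates symmetric positive", {
  set.seed(44)
  d <- make_twin_pairs(300, sigma2 = 1)
  for (fn in list(fit_logistic, fit_glmm_pql, fit_glmm_agq,
                  fit_gee_exchangeable)) {
    f1 <- fn(d, "x"); f2 <- fn(d, "x")
    expect_identical(f1$coefficients, f2$coefficients)
    expect_equal(f1$vcov, t(f1$vcov))
    expect_true(all(diag(f1$vcov) > 0))
    expect_true(all(f1$se > 0))
  }
})

test_that("clusters of size three are rejected", {
  d <- data.frame(cluster_id = c(1, 1, 1, 2), member = c(1, 2, 3, 1),
                  x = rnorm(4), y = c(0, 1, 0, 1))
  expect_error(fit_logistic(d, "x"), "size 3")
})

test_that("the formula front-end dispatches and the S3 methods work", {
  set.seed(45)
  spec <- ukos_outcome_spec("death", 2, sigma2 = 1)
  d <- simulate_dataset(scenario(200, 0.1, spec, n_reps = 1), 1)
  f <- cluster_logit(y ~ bweight + sex, d, method = "gee")
  expect_s3_class(f, "cluster_fit")
  expect_identical(f$method, "gee")
  expect_named(coef(f), c("(Intercept)", "bweight", "sex"))
  expect_equal(dim(vcov(f)), c(3L, 3L))
  ci <- confint(f)
  expect_true(all(ci[, 1] < coef(f) & coef(f) < ci[, 2]))
  expect_output(print(summary(f)), "exchangeable")
  fa <- cluster_logit(y ~ bweight + sex, d, method = "agq")
  expect_false(is.na(logLik(fa)))
  expect_error(cluster_logit(y ~ log(bweight), d), "plain covariate")
})
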