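test_that("cluster allocation rounds the twin count half away from zero", {
  expect_equal(allocate_clusters(150, 0.02)[c("n_singletons", "n_twin_pairs")],
               list(n_singletons = 147L, n_twin_pairs = 3L))
  expect_equal(allocate_clusters(150, 0.20)[c("n_singletons", "n_twin_pairs")],
               list(n_singletons = 120L, n_twin_pairs = 30L))
  expect_equal(allocate_clusters(1000, 0.05)[c("n_singletons", "n_twin_pairs")],
               list(n_singletons = 950L, n_twin_pairs = 50L))
  expect_equal(allocate_clusters(150, 0.05)$n_twin_pairs, 8L)  # 7.5 -> 8
  expect_equal(allocate_clusters(150, 0.2)$n_obs, 180L)
  expect_error(allocate_clusters(-5, 0.1), "n_clusters")
  expect_error(allocate_clusters(100, 1.2), "twin_fraction")
})

test_that("categorical profile draws follow the probability table", {
  expect_identical(draw_categorical_profiles(0, c(0.3, 0.7)), integer(0))
  expect_identical(draw_categorical_profiles(5, 1), rep(1L, 5L))
  set.seed(101)
  draws <- draw_categorical_profiles(100000, c(0.5, 0.5))
  expect_true(abs(mean(draws == 1L) - 0.5) < 0.01)
  expect_error(draw_categorical_profiles(3, numeric(0)), "empty")
  expect_error(draw_categorical_profiles(3, c(0.5, 0.6)), "sum to 1")
})

test_that("continuous covariates respect profile means and cross-sibling correlation", {
  m <- tiny_covariate_model(bw_corr = 0.7)
  # degenerate normal: zero covariance returns the mean exactly
  m0 <- m
  m0$mvn[["sex=0"]]$singleton$cov[] <- 0
  set.seed(1)
  x <- draw_continuous_covariates("sex=0", "singleton", m0)
  expect_equal(unname(x[1, "bweight"]), 750)

  set.seed(2)
  frame <- twinsim:::simulate_covariate_frame(m, 0, 50000)
  bw1 <- frame$bweight[frame$member == 1]
  bw2 <- frame$bweight[frame$member == 2]
  expect_equal(cor(bw1, bw2), 0.7, tolerance = 0.01)

  # one-at-a-time interface agrees in distribution (CLT bound on the mean)
  set.seed(3)
  draws <- replicate(20000, draw_continuous_covariates("sex=1", "singleton",
                                                       m)[1, 1])
  expect_lt(abs(mean(draws) - 790), 4 * 150 / sqrt(20000))

  expect_error(draw_continuous_covariates("sex=9", "singleton", m),
               "sex=9")
})

test_that("Apgar truncation matches the stated folding rule and is idempotent", {
  expect_equal(apply_apgar_truncation(13.4), 10)
  expect_equal(apply_apgar_truncation(11.2), 9)
  expect_equal(apply_apgar_truncation(7.5), 7.5)
  expect_equal(apply_apgar_truncation(c(12, 10, 10.0001, 12.0001)),
               c(9, 10, 9, 10))
  v <- seq(-5, 20, by = 0.01)
  out <- apply_apgar_truncation(v)
  expect_true(all(out <= 10))
  # the folded range (10, 12] and everything above it never survive;
  # values at or below 10 (including fractional ones) pass through
  expect_false(any(out > 10))
  expect_false(any(out > 10 & out <= 12))
  expect_equal(apply_apgar_truncation(out), out)  # idempotent
})

test_that("random intercepts are N(0, sigma2) with exact zeros at sigma2 = 0", {
  expect_identical(simulate_random_intercepts(10, 0), rep(0, 10))
  set.seed(4)
  u <- simulate_random_intercepts(100000, 2)
  expect_equal(var(u), 2, tolerance = 0.05)
  set.seed(9); a <- simulate_random_intercepts(50, 1.3)
  set.seed(9); b <- simulate_random_intercepts(50, 1.3)
  expect_identical(a, b)
  expect_error(simulate_random_intercepts(10, -1), "non-negative")
})

test_that("outcome probability is the stable inverse logit of the linear predictor", {
  sp0 <- outcome_spec("null", c("(Intercept)" = 0, x = 0))
  expect_equal(outcome_probability(c(x = 3), 0, sp0), 0.5)

  sp <- ukos_outcome_spec("death", 2)
  # eta = 3.037 - 0.006*800 + 0.598 = -1.165
  p <- outcome_probability(c(bweight = 800, sex = 1), 0, sp)
  expect_equal(p, stats::plogis(-1.165), tolerance = 1e-12)
  expect_equal(p, 0.23776, tolerance = 1e-4)  # 1/(1 + e^1.165)

  big <- outcome_spec("sat", c("(Intercept)" = -800, x = 0))
  expect_identical(outcome_probability(c(x = 0), 0, big), 0)
  expect_error(outcome_probability(c(z = 1), 0, sp), "bweight")
})

test_that("Bernoulli outcome draws behave at the boundaries and in the mean", {
  expect_identical(draw_outcomes(rep(0, 50)), rep(0L, 50))
  expect_identical(draw_outcomes(rep(1, 50)), rep(1L, 50))
  set.seed(6)
  expect_equal(mean(draw_outcomes(rep(0.3, 100000))), 0.3,
               tolerance = 0.01)
  expect_error(draw_outcomes(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("simulated datasets have the scenario's cluster structure and are reproducible", {
  spec <- ukos_outcome_spec("death", 2, sigma2 = 1)
  sc0 <- scenario(80, 0, spec, n_reps = 1)
  d0 <- simulate_dataset(sc0, 1)
  expect_equal(nrow(d0), 80)
  expect_true(all(table(d0$cluster_id) == 1))

  sc <- scenario(150, 0.2, spec, n_reps = 2)
  d <- simulate_dataset(sc, 1)
  expect_equal(nrow(d), 180)
  expect_equal(length(unique(d$cluster_id)), 150)
  sizes <- table(d$cluster_id)
  expect_true(all(sizes %in% 1:2))
  expect_equal(sum(sizes == 2), 30)
  # members unique within cluster, no missing covariates
  expect_false(any(duplicated(d[, c("cluster_id", "member")])))
  expect_false(anyNA(d))
  # twins share their categorical profile
  pairs <- d[d$cluster_id %in% names(sizes)[sizes == 2], ]
  agg <- aggregate(sex ~ cluster_id, pairs, function(s) length(unique(s)))
  expect_true(all(agg$sex == 1))

  d_again <- simulate_dataset(sc, 1)
  expect_identical(d, d_again)
  d2 <- simulate_dataset(sc, 2)
  expect_false(identical(d$y, d2$y))
})

test_that("within-pair outcome correlation increases with the random-intercept variance", {
  m <- tiny_covariate_model()
  cors <- vapply(c(0, 0.5, 2), function(s2) {
    spec <- outcome_spec("t", c("(Intercept)" = -0.5, bweight = 0.002,
                                sex = 0.3), sigma2 = s2)
    sc <- scenario(50000, 1, spec, covariate_model = m, n_reps = 1,
                   master_seed = 77)
    d <- simulate_dataset(sc, 1)
    y1 <- d$y[d$member == 1]; y2 <- d$y[d$member == 2]
    cor(y1, y2)
  }, numeric(1))
  expect_lt(abs(cors[1]), 0.02)           # conditional independence
  expect_true(all(diff(cors) > 0))        # strictly ordered in sigma2
})

test_that("intercept calibration hits the target prevalence and is monotone", {
  m <- tiny_covariate_model()
  spec <- outcome_spec("t", c("(Intercept)" = -1, bweight = 0.001),
                       sigma2 = 0.5)
  b1 <- calibrate_intercept(m, spec, 0.3, n_mc = 50000, seed = 8)
  spec2 <- spec; spec2$coefficients[["(Intercept)"]] <- as.numeric(b1)
  # fixed point: recalibrating to the achieved prevalence returns ~b1
  b2 <- calibrate_intercept(m, spec2, attr(b1, "prevalence"),
                            n_mc = 50000, seed = 8)
  expect_equal(as.numeric(b2), as.numeric(b1), tolerance = 1e-6)
  # monotone in the target
  b_lo <- calibrate_intercept(m, spec, 0.2, n_mc = 50000, seed = 8)
  b_hi <- calibrate_intercept(m, spec, 0.5, n_mc = 50000, seed = 8)
  expect_true(as.numeric(b_lo) < as.numeric(b1) &&
                as.numeric(b1) < as.numeric(b_hi))
  expect_error(calibrate_intercept(m, spec, 0.3, n_mc = 50000, seed = 8,
                                   interval = c(-60, -50)),
               "calibration error")
  expect_error(calibrate_intercept(m, spec, 1.2, n_mc = 50000), "0, 1")
})

test_that("calibrated death model reproduces the cohort prevalence in fresh simulation", {
  spec <- calibrated_outcome_spec("death", 4, sigma2 = 1, n_mc = 100000,
                                  seed = 21)
  sc <- scenario(60000, 0.1, spec, n_reps = 1, master_seed = 22)
  d <- simulate_dataset(sc, 1)
  expect_equal(mean(d$y), 0.26, tolerance = 0.01)
})

test_that("dataset CSV round-trips", {
  spec <- ukos_outcome_spec("o2dep", 2, sigma2 = 0.5)
  d <- simulate_dataset(scenario(60, 0.1, spec, n_reps = 1), 1)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(back$y, d$y)
  expect_equal(back$bweight, d$bweight, tolerance = 1e-12)
  expect_error(read_dataset(write_dataset(d[, -1], tempfile())),
               "cluster_id")
})
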