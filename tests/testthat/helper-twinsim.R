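# Shared test fixtures, built in code.

# A minimal one-covariate model: single profile (sex), birthweight only.
tiny_covariate_model <- function(bw_corr = 0.7) {
  profiles <- data.frame(sex = 0:1, prob_singleton = c(0.5, 0.5),
                         prob_twin = c(0.5, 0.5))
  mvn <- list()
  for (s in 0:1) {
    mu <- 750 + 40 * s
    shared <- bw_corr * 150^2
    indiv <- (1 - bw_corr) * 150^2
    cov_pair <- matrix(shared, 2, 2) + diag(indiv, 2)
    mvn[[paste0("sex=", s)]] <- list(
      singleton = list(mean = c(bweight = mu),
                       cov = matrix(150^2, 1, 1,
                                    dimnames = list("bweight", "bweight"))),
      twin_pair = list(mean = c(bweight.1 = mu, bweight.2 = mu),
                       cov = cov_pair))
  }
  covariate_model("bweight", "sex", profiles, mvn)
}

# Paired binary data generated directly from the random-intercept model
# with a single binary covariate; used for estimator recovery checks.
make_twin_pairs <- function(n_pairs, beta0 = -0.5, beta1 = 0.8,
                            sigma2 = 1) {
  x <- stats::rbinom(n_pairs, 1, 0.5)
  u <- stats::rnorm(n_pairs, 0, sqrt(sigma2))
  d <- data.frame(cluster_id = rep(seq_len(n_pairs), each = 2),
                  member = rep(1:2, n_pairs),
                  x = rep(x, each = 2))
  d$y <- stats::rbinom(2 * n_pairs, 1,
                       stats::plogis(beta0 + beta1 * d$x +
                                       rep(u, each = 2)))
  d
}

# Independent (singleton) logistic data.
make_iid_logistic <- function(n, beta0 = -0.4, beta1 = 0.7) {
  x <- stats::rnorm(n)
  data.frame(cluster_id = seq_len(n), member = 1L,
             y = stats::rbinom(n, 1, stats::plogis(beta0 + beta1 * x)),
             x = x)
}

# Brute-force marginal log-likelihood of the random-intercept logistic
# model by trapezoid integration over u in [-10 sigma, 10 sigma];
# independent oracle for the adaptive quadrature.
brute_marginal_loglik <- function(data, beta, sigma2, covariates,
                                  n_grid = 10001L) {
  X <- cbind(1, as.matrix(data[, covariates, drop = FALSE]))
  eta <- drop(X %*% beta)
  s <- sqrt(sigma2)
  u <- seq(-10 * s, 10 * s, length.out = n_grid)
  du <- u[2L] - u[1L]
  ll <- 0
  for (cl in unique(data$cluster_id)) {
    idx <- which(data$cluster_id == cl)
    lf <- stats::dnorm(u, 0, s, log = TRUE)
    for (i in idx) {
      e <- eta[i] + u
      lf <- lf + data$y[i] * e - log1p(exp(e))
    }
    mx <- max(lf)
    ll <- ll + mx + log(sum(exp(lf - mx)) * du)
  }
  ll
}

# Build a slim converged fit object for evaluation-layer tests.
stub_fit <- function(coefs, ses, sigma2 = NA_real_, converged = TRUE,
                     method = "logistic") {
  structure(list(method = method, coefficients = coefs, se = ses,
                 sigma2 = sigma2, converged = converged,
                 diagnostics = character()),
            class = "cluster_fit")
}
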