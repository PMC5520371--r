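#' Split a cluster count into singletons and twin pairs
#'
#' The twin percentage of a scenario is interpreted as the fraction of
#' CLUSTERS that are twin pairs; the number of pairs is rounded
#' half-away-from-zero so e.g. 2% of 150 clusters gives exactly 3 pairs.
#'
#' @param n_clusters Total number of clusters (births), `>= 1`.
#' @param twin_fraction Fraction of clusters of size two, in `[0, 1]`.
#' @return A named list with `n_singletons`, `n_twin_pairs` and `n_obs`
#'   (total infants, `n_singletons + 2 * n_twin_pairs`).
#' @examples
#' allocate_clusters(150, 0.02)  # 147 singletons, 3 twin pairs
#' @export
allocate_clusters <- function(n_clusters, twin_fraction) {
  if (!is.numeric(n_clusters) || n_clusters < 1)
    stop("'n_clusters' must be >= 1")
  if (!is.numeric(twin_fraction) || twin_fraction < 0 || twin_fraction > 1)
    stop("'twin_fraction' must be in [0, 1]")
  # round half away from zero (base round() rounds half to even)
  n_t <- as.integer(floor(twin_fraction * n_clusters + 0.5))
  n_s <- as.integer(n_clusters) - n_t
  list(n_singletons = n_s, n_twin_pairs = n_t, n_obs = n_s + 2L * n_t)
}

#' Draw categorical covariate profiles
#'
#' One profile is drawn per cluster from a multinomial distribution; twins
#' of a pair share their cluster's profile (so siblings share sex and
#' maternal smoking status).
#'
#' @param n_draws Number of profiles to draw (one per cluster).
#' @param probs Probability vector over profiles (must sum to 1).
#' @return Integer vector of profile indices of length `n_draws`.
#' @export
draw_categorical_profiles <- function(n_draws, probs) {
  if (length(probs) == 0L) stop("empty profile probability table")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12)
    stop("profile probabilities must be non-negative and sum to 1")
  if (n_draws == 0L) return(integer(0))
  sample.int(length(probs), size = n_draws, replace = TRUE, prob = probs)
}

# Vectorized multivariate-normal draws: n rows from N(mean, cov).
draw_mvn <- function(n, mean, cov) {
  k <- length(mean)
  L <- psd_chol(as.matrix(cov))
  z <- matrix(stats::rnorm(n * k), nrow = k)
  t(L %*% z + mean)
}

#' Draw continuous covariates for one cluster
#'
#' For a singleton, one draw from the profile's k-dimensional normal; for a
#' twin pair, one draw from the joint 2k-dimensional normal (both siblings
#' jointly, preserving cross-sibling correlation), returned as two rows.
#' Truncation rules are applied afterwards.
#'
#' @param profile Profile id string (see [profile_id()]) or profile row
#'   index into `model$profiles`.
#' @param cluster_kind `"singleton"` or `"twin_pair"`.
#' @param model A [covariate_model()].
#' @return A 1- or 2-row matrix with columns `model$continuous`.
#' @export
draw_continuous_covariates <- function(profile, cluster_kind, model) {
  cluster_kind <- match.arg(cluster_kind, c("singleton", "twin_pair"))
  if (is.numeric(profile))
    profile <- profile_id(model, model$profiles[profile, , drop = FALSE])
  blk <- model$mvn[[profile]]
  if (is.null(blk))
    stop("no multivariate-normal parameters for profile '", profile, "'")
  b <- blk[[cluster_kind]]
  k <- length(model$continuous)
  x <- draw_mvn(1L, b$mean, b$cov)
  out <- if (cluster_kind == "singleton") x else
    rbind(x[1, seq_len(k)], x[1, k + seq_len(k)])
  colnames(out) <- model$continuous
  apply_truncation_rules(out, model)
}

# Apply the model's truncation rules column-wise.
apply_truncation_rules <- function(x, model) {
  for (nm in names(model$truncation)) {
    if (!nm %in% colnames(x)) next
    rule <- model$truncation[[nm]]$rule
    if (identical(rule, "apgar")) {
      x[, nm] <- apply_apgar_truncation(x[, nm])
    } else {
      stop("unknown truncation rule '", rule, "' for covariate ", nm)
    }
  }
  x
}

#' Truncate simulated Apgar scores
#'
#' Simulated Apgar values are drawn from a normal distribution and then
#' folded back into the admissible score range: values above 12 are
#' replaced by 10 and values in `(10, 12]` by 9; values at or below 10 are
#' unchanged (scores stay continuous). The rule is idempotent and its
#' output never exceeds 10 and never falls in `(9, 10)`.
#'
#' @param value Numeric vector of scores.
#' @return Truncated scores.
#' @examples
#' apply_apgar_truncation(c(13.4, 11.2, 7.5))  # 10, 9, 7.5
#' @export
apply_apgar_truncation <- function(value) {
  out <- value
  out[value > 12] <- 10
  out[value > 10 & value <= 12] <- 9
  out
}

#' Draw cluster-level random intercepts
#'
#' One i.i.d. `N(0, sigma2)` deviate per cluster, shared by both twins of a
#' pair; `sigma2 = 0` gives exact zeros.
#'
#' @param n_clusters Number of clusters.
#' @param sigma2 Random-intercept variance, `>= 0`.
#' @return Numeric vector of length `n_clusters`.
#' @export
simulate_random_intercepts <- function(n_clusters, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) ||
      sigma2 < 0)
    stop("'sigma2' must be a single non-negative number")
  if (sigma2 == 0) return(rep(0, n_clusters))
  stats::rnorm(n_clusters, mean = 0, sd = sqrt(sigma2))
}

#' Outcome probability under the two-level logit model
#'
#' Evaluates `p = logit^-1(beta0 + u0 + sum_k beta_k x_k)`; numerically
#' stable for arbitrarily large `|eta|` (saturates to 0/1 without
#' overflow).
#'
#' @param covariates Named numeric vector, or a data.frame/matrix with one
#'   row per infant, containing every covariate the model names.
#' @param u0 Cluster random effect(s), recycled against rows.
#' @param spec An [outcome_spec()].
#' @return Probability vector.
#' @examples
#' sp <- ukos_outcome_spec("death", 2)
#' outcome_probability(c(bweight = 800, sex = 1), 0, sp)  # ~0.238
#' @export
outcome_probability <- function(covariates, u0, spec) {
  beta <- spec$coefficients
  vars <- setdiff(names(beta), "(Intercept)")
  if (is.null(dim(covariates)))
    covariates <- matrix(covariates, nrow = 1L,
                         dimnames = list(NULL, names(covariates)))
  covariates <- as.matrix(as.data.frame(covariates)[, , drop = FALSE])
  miss <- setdiff(vars, colnames(covariates))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  eta <- beta[["(Intercept)"]] + u0 +
    drop(covariates[, vars, drop = FALSE] %*% beta[vars])
  inv_logit(eta)
}

#' Draw Bernoulli outcomes
#'
#' @param probabilities Vector of probabilities in `[0, 1]`; conditional on
#'   the cluster effects the draws are independent.
#' @return Integer 0/1 vector.
#' @export
draw_outcomes <- function(probabilities) {
  if (any(is.na(probabilities)) || any(probabilities < 0) ||
      any(probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  stats::rbinom(length(probabilities), 1L, probabilities)
}

# Simulate the covariate frame for n_s singletons and n_t twin pairs.
# Returns a data.frame: cluster_id, member, categorical and continuous
# covariate columns; clusters 1..n_s are singletons.
simulate_covariate_frame <- function(model, n_s, n_t) {
  k <- length(model$continuous)
  ids <- vapply(seq_len(nrow(model$profiles)),
                function(i) profile_id(model, model$profiles[i, , drop = FALSE]),
                character(1))
  prof_s <- draw_categorical_profiles(n_s, model$profiles$prob_singleton)
  prof_t <- draw_categorical_profiles(n_t, model$profiles$prob_twin)

  xs <- matrix(NA_real_, n_s, k)
  if (n_s > 0) {
    for (g in unique(prof_s)) {
      idx <- which(prof_s == g)
      b <- model$mvn[[ids[g]]]$singleton
      xs[idx, ] <- draw_mvn(length(idx), b$mean, b$cov)
    }
  }
  x1 <- matrix(NA_real_, n_t, k)
  x2 <- matrix(NA_real_, n_t, k)
  if (n_t > 0) {
    for (g in unique(prof_t)) {
      idx <- which(prof_t == g)
      b <- model$mvn[[ids[g]]]$twin_pair
      xx <- draw_mvn(length(idx), b$mean, b$cov)
      x1[idx, ] <- xx[, seq_len(k), drop = FALSE]
      x2[idx, ] <- xx[, k + seq_len(k), drop = FALSE]
    }
  }
  cont <- rbind(xs, x1, x2)[order(c(seq_len(n_s),
                                    n_s + seq_len(n_t),
                                    n_s + seq_len(n_t)),
                                  c(rep(1L, n_s), rep(1L, n_t),
                                    rep(2L, n_t))), , drop = FALSE]
  colnames(cont) <- model$continuous
  cont <- apply_truncation_rules(cont, model)

  cluster_id <- c(seq_len(n_s), rep(n_s + seq_len(n_t), each = 2L))
  member <- c(rep(1L, n_s), rep(c(1L, 2L), n_t))
  prof_row <- c(prof_s, rep(prof_t, each = 2L))
  cat_cols <- model$profiles[prof_row, model$categorical, drop = FALSE]
  rownames(cat_cols) <- NULL
  df <- data.frame(cluster_id = cluster_id, member = member,
                   cat_cols, cont, check.names = FALSE)
  rownames(df) <- NULL
  df
}

#' Simulation scenario
#'
#' Bundles everything needed to generate replicate datasets: the cluster
#' count, the fraction of twin-pair clusters, the outcome-generating model,
#' the covariate model, the replicate count and the master seed. Replicate
#' `r` of a scenario is generated from the seed
#' `replicate_seed(master_seed, id, r)`, so any replicate is reproducible
#' in isolation.
#'
#' @param n_clusters Number of clusters (e.g. 150, 500, 1000).
#' @param twin_fraction Fraction of clusters of size two (0 to 1; the study
#'   grid uses 0.02 to 0.20).
#' @param outcome_spec An [outcome_spec()]; its `sigma2` is the scenario's
#'   random-intercept variance.
#' @param covariate_model A [covariate_model()]; defaults to the packaged
#'   synthetic preterm-cohort model.
#' @param n_reps Number of Monte-Carlo replicates (the full study uses
#'   5000).
#' @param master_seed Integer master seed.
#' @param id Scenario identifier; derived from the fields when `NULL`.
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(n_clusters, twin_fraction, outcome_spec,
                     covariate_model = ukos_covariate_model(),
                     n_reps = 5000L, master_seed = 20170720L, id = NULL) {
  stopifnot(inherits(outcome_spec, "outcome_spec"),
            inherits(covariate_model, "covariate_model"))
  if (twin_fraction < 0 || twin_fraction > 1)
    stop("'twin_fraction' must be in [0, 1]")
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  n_cov <- length(outcome_spec$coefficients) - 1L
  if (is.null(id))
    id <- sprintf("%s%d_c%d_tw%g_v%g", outcome_spec$outcome_name, n_cov,
                  as.integer(n_clusters), twin_fraction,
                  outcome_spec$sigma2)
  structure(list(n_clusters = as.integer(n_clusters),
                 twin_fraction = twin_fraction,
                 outcome_spec = outcome_spec,
                 covariate_model = covariate_model,
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed),
                 id = id),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$id, "\n")
  cat(sprintf("  %d clusters, %.0f%% twin pairs, sigma2 = %g, outcome %s (%d covariates)\n",
              x$n_clusters, 100 * x$twin_fraction, x$outcome_spec$sigma2,
              x$outcome_spec$outcome_name,
              length(x$outcome_spec$coefficients) - 1L))
  cat(sprintf("  %d replicates, master seed %d\n", x$n_reps, x$master_seed))
  invisible(x)
}

#' Generate one replicate dataset of a scenario
#'
#' Composes the generator steps: allocate clusters, draw one categorical
#' profile per cluster, draw continuous covariates (jointly over both twins
#' of a pair), apply truncation rules, draw one random intercept per
#' cluster, evaluate the two-level logit model and draw Bernoulli outcomes.
#' The result is byte-identical for a fixed (master seed, scenario id,
#' replicate index).
#'
#' @param scenario A [scenario()].
#' @param replicate_index Replicate number (1-based).
#' @return A data.frame in long format with columns `cluster_id`, `member`,
#'   `y` and one column per covariate; attributes `scenario_id`,
#'   `replicate` and `seed` record provenance.
#' @export
simulate_dataset <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "scenario"))
  seed <- replicate_seed(scenario$master_seed, scenario$id, replicate_index)
  set.seed(seed)
  alloc <- allocate_clusters(scenario$n_clusters, scenario$twin_fraction)
  df <- simulate_covariate_frame(scenario$covariate_model,
                                 alloc$n_singletons, alloc$n_twin_pairs)
  u0 <- simulate_random_intercepts(scenario$n_clusters,
                                   scenario$outcome_spec$sigma2)
  p <- outcome_probability(df[, -(1:2), drop = FALSE], u0[df$cluster_id],
                           scenario$outcome_spec)
  df <- data.frame(cluster_id = df$cluster_id, member = df$member,
                   y = draw_outcomes(p), df[, -(1:2), drop = FALSE],
                   check.names = FALSE)
  attr(df, "scenario_id") <- scenario$id
  attr(df, "replicate") <- as.integer(replicate_index)
  attr(df, "seed") <- seed
  df
}

#' Read / write a simulated dataset as CSV
#'
#' Long-format exchange: header `cluster_id,member,y,<covariates>`, one row
#' per infant, UTF-8, "." decimal separator.
#'
#' @param data A dataset as returned by [simulate_dataset()].
#' @param path File path.
#' @return `read_dataset()` returns a data.frame; `write_dataset()` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("cluster_id", "member", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  df
}
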