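# Scenario-grid orchestration: run replicates with managed seeds, fit the
# requested methods to each simulated dataset, and reduce to the
# per-scenario metric summaries.

method_fitters <- list(
  logistic = function(data, covars) fit_logistic(data, covars),
  pql = function(data, covars) fit_glmm_pql(data, covars),
  agq = function(data, covars) fit_glmm_agq(data, covars),
  gee = function(data, covars) fit_gee_exchangeable(data, covars))

# Strip a fit down to what the evaluation layer needs (keeps the raw
# replicate store small at 5000 replicates x 4 methods).
slim_fit <- function(fit) {
  structure(list(method = fit$method, coefficients = fit$coefficients,
                 se = fit$se, sigma2 = fit$sigma2,
                 sigma2_se = fit$sigma2_se, converged = fit$converged,
                 diagnostics = fit$diagnostics),
            class = "cluster_fit")
}

#' Run all replicates of one scenario
#'
#' For each replicate: simulate a dataset (seeded by
#' [replicate_seed()], so results do not depend on execution order or the
#' number of workers), fit every requested method to the SAME dataset,
#' apply the divergence filter, and collect estimates. Per-replicate fit
#' failures are recorded as non-convergence and never abort the run.
#'
#' @param scenario A [scenario()].
#' @param methods Subset of `c("logistic", "pql", "agq", "gee")`.
#' @param workers Number of parallel workers (forked; results are reduced
#'   in replicate order regardless of completion order).
#' @param parameters Coefficients to summarise (default all).
#' @return An object of class `"scenario_result"`: list with `scenario`,
#'   `fits` (method -> list of slim fits), `raw` (long data.frame of
#'   replicate estimates) and `summary` (from [summarize_scenario()]).
#' @export
run_scenario <- function(scenario,
                         methods = c("logistic", "pql", "agq", "gee"),
                         workers = 1L, parameters = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  methods <- match.arg(methods, several.ok = TRUE)
  covars <- setdiff(names(scenario$outcome_spec$coefficients),
                    "(Intercept)")

  one_rep <- function(r) {
    dat <- simulate_dataset(scenario, r)
    lapply(method_fitters[methods], function(fitter) {
      fit <- tryCatch(fitter(dat, covars), error = function(e)
        new_cluster_fit("failed",
                        coefficients = stats::setNames(
                          rep(NA_real_, length(covars) + 1L),
                          c("(Intercept)", covars)),
                        se = stats::setNames(
                          rep(NA_real_, length(covars) + 1L),
                          c("(Intercept)", covars)),
                        converged = FALSE,
                        diagnostics = conditionMessage(e)))
      slim_fit(apply_divergence_filter(fit))
    })
  }
  reps <- seq_len(scenario$n_reps)
  per_rep <- if (workers > 1L) {
    parallel::mclapply(reps, one_rep, mc.cores = workers)
  } else {
    lapply(reps, one_rep)
  }
  fits <- lapply(methods, function(m) lapply(per_rep, `[[`, m))
  names(fits) <- methods

  raw <- do.call(rbind, lapply(seq_along(per_rep), function(r) {
    do.call(rbind, lapply(methods, function(m) {
      f <- per_rep[[r]][[m]]
      data.frame(scenario = scenario$id, replicate = r, method = m,
                 parameter = names(f$coefficients),
                 estimate = unname(f$coefficients), se = unname(f$se),
                 sigma2 = f$sigma2, converged = f$converged,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  summ <- summarize_scenario(fits, scenario, parameters)
  n_cov <- length(covars)
  meta <- data.frame(n_clusters = scenario$n_clusters,
                     twin_pct = 100 * scenario$twin_fraction,
                     sigma2_true = scenario$outcome_spec$sigma2,
                     outcome = scenario$outcome_spec$outcome_name,
                     n_covariates = n_cov)
  summ <- cbind(summ, meta[rep(1L, nrow(summ)), , drop = FALSE])
  rownames(summ) <- NULL
  structure(list(scenario = scenario, fits = fits, raw = raw,
                 summary = summ),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  cat("\nSummary (birthweight row shown if present):\n")
  sub <- x$summary[x$summary$parameter %in% c("bweight"), , drop = FALSE]
  if (!nrow(sub)) sub <- x$summary
  print(sub[, c("method", "parameter", "rel_bias", "emp_bias", "coverage",
                "mse", "nonconv_pct", "n_converged")], digits = 3)
  invisible(x)
}

#' Scenario grid specification
#'
#' Defaults mirror the study design: 150/500/1000 clusters, 2-20% twin
#' pairs, random-intercept variances 0.5/1/2 (4 and 8 available as an
#' extension), both outcomes, 2 and 4 covariates, 5000 replicates.
#'
#' @param n_clusters_list,twin_pct_list,variance_list,outcomes,covariate_counts
#'   Grid axes (`twin_pct_list` in percent, 0-100).
#' @param n_reps Replicates per scenario.
#' @param master_seed Master seed.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(n_clusters_list = c(150, 500, 1000),
                      twin_pct_list = c(2, 5, 10, 20),
                      variance_list = c(0.5, 1, 2),
                      outcomes = c("death", "o2dep"),
                      covariate_counts = c(2, 4),
                      n_reps = 5000L, master_seed = 20170720L) {
  stopifnot(length(n_clusters_list) > 0, length(twin_pct_list) > 0,
            length(variance_list) > 0, length(outcomes) > 0,
            length(covariate_counts) > 0, n_reps >= 1)
  structure(list(n_clusters_list = n_clusters_list,
                 twin_pct_list = twin_pct_list,
                 variance_list = variance_list,
                 outcomes = outcomes,
                 covariate_counts = covariate_counts,
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed)),
            class = "grid_spec")
}

# Expand a grid_spec into scenario objects, calibrating each outcome /
# covariate-count / variance combination's intercept once.
scenarios_from_grid <- function(grid, covariate_model = ukos_covariate_model(),
                                calibrate = TRUE) {
  combos <- expand.grid(n_clusters = grid$n_clusters_list,
                        twin_pct = grid$twin_pct_list,
                        variance = grid$variance_list,
                        outcome = grid$outcomes,
                        n_cov = grid$covariate_counts,
                        stringsAsFactors = FALSE)
  spec_cache <- new.env(parent = emptyenv())
  get_spec <- function(outcome, n_cov, v) {
    key <- paste(outcome, n_cov, v, sep = "_")
    if (is.null(spec_cache[[key]])) {
      spec_cache[[key]] <- if (calibrate)
        calibrated_outcome_spec(outcome, n_cov, sigma2 = v,
                                model = covariate_model,
                                seed = grid$master_seed)
      else ukos_outcome_spec(outcome, n_cov, sigma2 = v)
    }
    spec_cache[[key]]
  }
  lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    scenario(cm$n_clusters, cm$twin_pct / 100,
             get_spec(cm$outcome, cm$n_cov, cm$variance),
             covariate_model = covariate_model,
             n_reps = grid$n_reps, master_seed = grid$master_seed)
  })
}

#' Run a scenario grid
#'
#' Runs [run_scenario()] over every cell of the grid and row-binds the
#' summaries. When `out_dir` is given the run is resumable: each
#' scenario's summary is written to `<out_dir>/<scenario id>.csv` on
#' completion and scenarios whose file already exists are skipped (their
#' summary is read back); raw replicate estimates are optionally retained
#' alongside.
#'
#' @param grid A [grid_spec()].
#' @param methods Methods to fit.
#' @param workers Parallel workers per scenario.
#' @param covariate_model Covariate model (packaged default).
#' @param calibrate Calibrate intercepts to the cohort prevalences
#'   (default `TRUE`).
#' @param out_dir Optional results/manifest directory.
#' @param keep_raw Also write replicate-level estimates
#'   (`<scenario>_raw.csv`) when `out_dir` is set.
#' @return Combined summary data.frame (one row per scenario, method,
#'   parameter).
#' @export
run_grid <- function(grid, methods = c("logistic", "pql", "agq", "gee"),
                     workers = 1L,
                     covariate_model = ukos_covariate_model(),
                     calibrate = TRUE, out_dir = NULL, keep_raw = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  scens <- scenarios_from_grid(grid, covariate_model, calibrate)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summaries <- lapply(scens, function(sc) {
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0(sc$id, ".csv"))
      if (file.exists(f)) {
        prev <- tryCatch(
          suppressWarnings(utils::read.csv(f, stringsAsFactors = FALSE)),
          error = function(e) NULL)
        need <- c("scenario", "method", "parameter", "emp_bias")
        if (is.null(prev) || !all(need %in% names(prev)))
          stop("corrupt manifest entry '", f, "'; delete it to re-run")
        return(prev)
      }
    }
    res <- run_scenario(sc, methods = methods, workers = workers)
    if (!is.null(out_dir)) {
      utils::write.csv(res$summary,
                       file.path(out_dir, paste0(sc$id, ".csv")),
                       row.names = FALSE)
      if (keep_raw)
        utils::write.csv(res$raw,
                         file.path(out_dir, paste0(sc$id, "_raw.csv")),
                         row.names = FALSE)
    }
    res$summary
  })
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  out
}

#' Arrange grid summaries as study-style tables
#'
#' Pivots the long summary table into the wide layouts used to report the
#' study: rows indexed by (twin percentage, random-intercept variance),
#' one column block per method. Styles: `"bias"` (empirical bias on the
#' x 10^4 scale with its 95% CI bounds), `"coverage"`, `"mse"`,
#' `"nonconvergence"` (percent) and `"variance"` (mean and SD of the
#' random-intercept variance estimate, mixed models only).
#'
#' @param summaries Data.frame from [run_grid()] / [run_scenario()].
#' @param style One of the table styles above.
#' @param parameter Coefficient to tabulate (default `"bweight"`).
#' @param path Optional CSV output path.
#' @return The wide data.frame (empty, header-only, if `summaries` has no
#'   matching rows).
#' @export
render_tables <- function(summaries,
                          style = c("bias", "coverage", "mse",
                                    "nonconvergence", "variance"),
                          parameter = "bweight", path = NULL) {
  style <- match.arg(style)
  methods <- unique(summaries$method)
  if (style == "variance")
    methods <- intersect(methods, c("pql", "agq"))
  sub <- summaries[summaries$parameter == parameter, , drop = FALSE]
  keys <- unique(sub[, c("outcome", "n_covariates", "n_clusters",
                         "twin_pct", "sigma2_true")])
  keys <- keys[order(keys$outcome, keys$n_covariates, keys$n_clusters,
                     keys$twin_pct, keys$sigma2_true), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    row <- k
    for (m in methods) {
      cell <- sub[sub$method == m &
                    sub$outcome == k$outcome &
                    sub$n_covariates == k$n_covariates &
                    sub$n_clusters == k$n_clusters &
                    sub$twin_pct == k$twin_pct &
                    sub$sigma2_true == k$sigma2_true, , drop = FALSE]
      vals <- switch(style,
        bias = {
          v <- c(NA_real_, NA_real_, NA_real_)
          if (nrow(cell))
            v <- 1e4 * c(cell$emp_bias, cell$ci_lo, cell$ci_hi)
          stats::setNames(v, paste0(m, c("_bias", "_lo", "_hi")))
        },
        coverage = stats::setNames(
          if (nrow(cell)) cell$coverage else NA_real_, m),
        mse = stats::setNames(
          if (nrow(cell)) cell$mse else NA_real_, m),
        nonconvergence = stats::setNames(
          if (nrow(cell)) cell$nonconv_pct else NA_real_, m),
        variance = {
          v <- c(NA_real_, NA_real_)
          if (nrow(cell)) v <- c(cell$var_mean, cell$var_sd)
          stats::setNames(v, paste0(m, c("_mean", "_sd")))
        })
      row <- cbind(row, as.data.frame(as.list(vals)))
    }
    row
  })
  if (length(rows)) {
    out <- do.call(rbind, rows)
  } else {
    cols <- switch(style,
                   bias = as.vector(outer(c("_bias", "_lo", "_hi"),
                                          methods,
                                          function(a, b) paste0(b, a))),
                   variance = as.vector(outer(c("_mean", "_sd"), methods,
                                              function(a, b) paste0(b, a))),
                   methods)
    out <- as.data.frame(matrix(numeric(0), nrow = 0,
                                ncol = 5 + length(cols)))
    names(out) <- c("outcome", "n_covariates", "n_clusters", "twin_pct",
                    "sigma2_true", cols)
  }
  rownames(out) <- NULL
  value_cols <- setdiff(names(out), c("outcome", "n_covariates",
                                      "n_clusters", "twin_pct",
                                      "sigma2_true"))
  if (nrow(out) && anyNA(out[, value_cols]))
    warning("rendered table has gaps (missing scenario/method cells)")
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
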