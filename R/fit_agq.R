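# log(1 + exp(x)) without overflow.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 37
  out[lo] <- log1p(exp(x[lo]))
  out
}

# Marginal log-likelihood of the random-intercept logistic model by
# adaptive Gauss-Hermite quadrature. Cluster sizes are 1 or 2, so the
# posterior-mode Newton search and the quadrature sum are fully vectorised
# across clusters: `o1`/`o2` are the linear predictors x_ij'beta of the
# first/second member (second arbitrary for singletons), `m2` a 0/1 vector
# flagging real second members. `u_start` warm-starts the mode search (the
# posterior mode is unique, so the result does not depend on the start).
agq_loglik <- function(o1, o2, y1, y2, m2, sigma, rule, u_start = NULL) {
  n <- length(o1)
  inv_s2 <- 1 / sigma^2
  u <- if (is.null(u_start)) numeric(n) else u_start
  for (it in 1:30) {
    p1 <- stats::plogis(o1 + u)
    p2 <- stats::plogis(o2 + u)
    score <- (y1 - p1) + m2 * (y2 - p2) - u * inv_s2
    info <- p1 * (1 - p1) + m2 * p2 * (1 - p2) + inv_s2
    step <- pmin(pmax(score / info, -5), 5)
    u <- u + step
    if (max(abs(step)) < 1e-10) break
  }
  p1 <- stats::plogis(o1 + u)
  p2 <- stats::plogis(o2 + u)
  info <- p1 * (1 - p1) + m2 * p2 * (1 - p2) + inv_s2
  tau <- 1 / sqrt(info)
  K <- rule$n_nodes
  terms <- matrix(0, n, K)
  log_norm <- -log(sigma) - 0.5 * log(2 * pi)
  for (k in seq_len(K)) {
    uk <- u + sqrt(2) * tau * rule$nodes[k]
    e1 <- o1 + uk; e2 <- o2 + uk
    lf <- y1 * e1 - log1pexp(e1) + m2 * (y2 * e2 - log1pexp(e2))
    terms[, k] <- log(rule$weights[k]) + rule$nodes[k]^2 + lf +
      log_norm - 0.5 * uk^2 * inv_s2
  }
  list(loglik = sum(log(sqrt(2) * tau) + log_sum_exp_rows(terms)),
       mode = u)
}

# Plain Bernoulli log-likelihood (the sigma = 0 limit).
bernoulli_loglik <- function(o1, o2, y1, y2, m2) {
  sum(y1 * o1 - log1pexp(o1) + m2 * (y2 * o2 - log1pexp(o2)))
}

#' Random-intercept logistic regression by adaptive Gauss-Hermite
#' quadrature
#'
#' Maximises the marginal log-likelihood
#' \deqn{\sum_i \log \int \prod_j \mathrm{Bern}(y_{ij};
#'   \mathrm{logit}^{-1}(x_{ij}'\beta + u))\,\phi(u; 0, \sigma^2)\,du,}
#' approximating each cluster's integral by adaptive Gauss-Hermite
#' quadrature: the rule is recentred at the cluster's posterior mode
#' (found by a vectorised Newton search) and rescaled by the curvature at
#' the mode, then evaluated at `rule$n_nodes` points (default 5 per axis).
#' The outer optimisation over \eqn{(\beta, \log\sigma)} uses a
#' quasi-Newton method with \eqn{\log\sigma} bounded below at -10;
#' hitting that bound is reported as \eqn{\hat\sigma^2 = 0} with a
#' boundary diagnostic rather than as a failure. Standard errors come from
#' the inverse of a numerically differentiated observed information.
#'
#' @inheritParams fit_logistic
#' @param rule A [gauss_hermite_rule()]; 1 node gives the Laplace
#'   approximation.
#' @param fix_sigma2 Optionally hold \eqn{\sigma^2} fixed; `0` collapses
#'   the integral to a point mass so the fit equals [fit_logistic()].
#' @param max_iter Iteration cap for the outer optimiser.
#' @return A `cluster_fit` with `sigma2`, its delta-method standard error
#'   `sigma2_se`, and `log_sigma`/`log_sigma_se` for interval construction
#'   on the better-behaved log scale.
#' @export
fit_glmm_agq <- function(data, covariates, cluster_col = "cluster_id",
                         y_col = "y", rule = gauss_hermite_rule(5),
                         fix_sigma2 = NULL, max_iter = 200L) {
  d <- prepare_design(data, covariates, cluster_col, y_col)
  ord <- order(d$cluster)
  d$y <- d$y[ord]; d$X <- d$X[ord, , drop = FALSE]
  d$cluster <- d$cluster[ord]
  sp <- split_by_size(d)
  X <- d$X; y <- d$y
  p <- ncol(X)
  # standardise covariate columns so the outer optimisation is well
  # conditioned (birthweight in grams vs indicator covariates spans three
  # orders of magnitude); estimates are transformed back afterwards
  ctr <- c(0, colMeans(X[, -1L, drop = FALSE]))
  scl <- c(1, apply(X[, -1L, drop = FALSE], 2L, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  Xs[, 1L] <- 1
  # beta = A %*% alpha for alpha on the standardised scale
  A <- diag(1 / scl)
  A[1L, ] <- c(1, -ctr[-1L] / scl[-1L])
  X_orig <- X
  X <- Xs
  n_s <- length(sp$s_idx); n_t <- length(sp$p1)
  n_clusters <- n_s + n_t
  # cluster-major layout: entry = cluster, member columns unrolled
  row1 <- c(sp$s_idx, sp$p1)
  row2 <- c(sp$s_idx, sp$p2)   # second member = first for singletons,
  m2 <- c(rep(0, n_s), rep(1, n_t))  # masked out by m2
  y1v <- y[row1]; y2v <- y[row2]
  X1 <- X[row1, , drop = FALSE]
  X2 <- X[row2, , drop = FALSE]

  fixed <- !is.null(fix_sigma2)
  u_warm <- NULL
  negll <- function(theta) {
    beta <- theta[seq_len(p)]
    o1 <- drop(X1 %*% beta); o2 <- drop(X2 %*% beta)
    ll <- if (fixed && fix_sigma2 == 0) {
      bernoulli_loglik(o1, o2, y1v, y2v, m2)
    } else {
      sigma <- if (fixed) sqrt(fix_sigma2) else exp(theta[p + 1L])
      res <- agq_loglik(o1, o2, y1v, y2v, m2, sigma, rule, u_warm)
      u_warm <<- res$mode
      res$loglik
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  start <- if (fixed) start_glm$coefficients else
    c(start_glm$coefficients, log(0.7))
  lower <- if (fixed) rep(-Inf, p) else c(rep(-Inf, p), -10)
  upper <- if (fixed) rep(Inf, p) else c(rep(Inf, p), 3)
  opt <- stats::nlminb(start, negll, lower = lower, upper = upper,
                       control = list(iter.max = max_iter,
                                      eval.max = 4L * max_iter,
                                      rel.tol = 1e-10))
  notes <- character()
  converged <- is.finite(opt$objective) && opt$objective < 1e10
  if (converged && opt$convergence != 0) {
    # "singular/false convergence" exits are common on flat likelihood
    # ridges; accept them only when the point is verifiably stationary
    g <- vapply(seq_along(opt$par), function(j) {
      h <- 1e-5 * (1 + abs(opt$par[j]))
      ej <- replace(numeric(length(opt$par)), j, h)
      at_bound <- opt$par[j] - h < lower[j] | opt$par[j] + h > upper[j]
      if (at_bound) 0 else (negll(opt$par + ej) - negll(opt$par - ej)) / (2 * h)
    }, numeric(1))
    if (max(abs(g)) < 1e-2) {
      notes <- paste0("optimizer exit '", opt$message,
                      "'; gradient check passed")
    } else {
      converged <- FALSE
      notes <- paste0("optimizer exit '", opt$message, "'")
    }
  }
  beta <- drop(A %*% opt$par[seq_len(p)])

  if (fixed) {
    sigma2 <- fix_sigma2; sigma2_se <- NA_real_
    log_sigma <- if (fix_sigma2 > 0) 0.5 * log(fix_sigma2) else -Inf
    log_sigma_se <- NA_real_
    H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
    vc_full <- if (is.null(H)) NULL else
      tryCatch(solve(H), error = function(e) NULL)
    vc <- vc_full
  } else {
    log_sigma <- unname(opt$par[p + 1L])
    boundary <- log_sigma <= -10 + 1e-6
    if (boundary) {
      sigma2 <- 0
      notes <- "variance estimate at boundary 0"
      # curvature in the sigma direction is degenerate at the bound;
      # report the fixed-effect information at sigma = 0
      negll_b <- function(b)
        -bernoulli_loglik(drop(X1 %*% b), drop(X2 %*% b), y1v, y2v, m2)
      H <- tryCatch(stats::optimHess(opt$par[seq_len(p)], negll_b),
                    error = function(e) NULL)
      vc <- if (is.null(H)) NULL else
        tryCatch(solve(H), error = function(e) NULL)
      sigma2_se <- NA_real_; log_sigma_se <- NA_real_
    } else {
      sigma2 <- unname(exp(2 * log_sigma))
      H <- tryCatch(stats::optimHess(opt$par, negll),
                    error = function(e) NULL)
      vc_full <- if (is.null(H)) NULL else
        tryCatch(solve(H), error = function(e) NULL)
      if (is.null(vc_full)) {
        vc <- NULL; sigma2_se <- NA_real_; log_sigma_se <- NA_real_
      } else {
        vc <- vc_full[seq_len(p), seq_len(p), drop = FALSE]
        log_sigma_se <- sqrt(max(vc_full[p + 1L, p + 1L], 0))
        sigma2_se <- 2 * sigma2 * log_sigma_se   # delta method
      }
    }
  }
  if (is.null(vc)) {
    vc <- matrix(NA_real_, p, p)
    converged <- FALSE
  } else {
    vc <- A %*% vc %*% t(A)       # back to the original covariate scale
    vc <- (vc + t(vc)) / 2
    if (any(diag(vc) <= 0)) {
      converged <- FALSE
      notes <- c(notes, "observed information not positive definite")
    }
  }
  dimnames(vc) <- list(colnames(X_orig), colnames(X_orig))
  new_cluster_fit("glmm_agq",
                  coefficients = stats::setNames(beta, colnames(X)),
                  se = stats::setNames(sqrt(pmax(diag(vc), 0)),
                                       colnames(X)),
                  vcov = vc, sigma2 = sigma2, sigma2_se = sigma2_se,
                  converged = converged,
                  n_iter = as.integer(opt$iterations),
                  loglik = -opt$objective, diagnostics = notes,
                  n_obs = length(y), n_clusters = n_clusters,
                  extra = list(log_sigma = if (fixed) log_sigma else
                    opt$par[p + 1L],
                    log_sigma_se = log_sigma_se,
                    n_nodes = rule$n_nodes))
}
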