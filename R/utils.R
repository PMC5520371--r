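# Internal numerical helpers.

# Numerically stable inverse logit; saturates cleanly for |eta| up to
# the largest double without overflow warnings.
inv_logit <- function(eta) stats::plogis(eta)

# log(sum(exp(x))) along rows of a matrix, guarding against underflow;
# column-wise pmax avoids the apply() overhead (few columns, many rows).
log_sum_exp_rows <- function(m) {
  mx <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, k])
  s <- exp(m[, 1L] - mx)
  for (k in seq_len(ncol(m))[-1L]) s <- s + exp(m[, k] - mx)
  mx + log(s)
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for integration against the weight function
#' \eqn{e^{-x^2}} (physicists' convention), computed from the eigen
#' decomposition of the Jacobi matrix (Golub-Welsch). Used by the adaptive
#' quadrature fitter for the random-intercept logistic model.
#'
#' @param n_nodes Number of quadrature nodes (default 5, the number of
#'   points per axis used throughout the simulation study; 1 node gives the
#'   Laplace approximation).
#' @param adaptive Logical flag recorded on the rule; the fitter recentres
#'   and rescales the rule at each cluster's posterior mode when `TRUE`.
#' @return An object of class `"quadrature_rule"`: a list with `nodes`
#'   (symmetric about 0), `weights` (positive, summing to \eqn{\sqrt\pi}),
#'   `n_nodes` and `adaptive`.
#' @examples
#' r <- gauss_hermite_rule(5)
#' sum(r$weights)            # sqrt(pi)
#' sum(r$weights * r$nodes^2) # sqrt(pi)/2
#' @export
gauss_hermite_rule <- function(n_nodes = 5L, adaptive = TRUE) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L)
    stop("'n_nodes' must be a positive integer")
  if (n_nodes == 1L) {
    nodes <- 0
    weights <- sqrt(pi)
  } else {
    k <- seq_len(n_nodes - 1L)
    jac <- matrix(0, n_nodes, n_nodes)
    jac[cbind(k, k + 1L)] <- sqrt(k / 2)
    jac[cbind(k + 1L, k)] <- sqrt(k / 2)
    e <- eigen(jac, symmetric = TRUE)
    ord <- order(e$values)
    nodes <- e$values[ord]
    weights <- sqrt(pi) * e$vectors[1L, ord]^2
    # enforce exact symmetry about zero
    nodes <- (nodes - rev(nodes)) / 2
    weights <- (weights + rev(weights)) / 2
  }
  structure(list(nodes = nodes, weights = weights,
                 n_nodes = n_nodes, adaptive = isTRUE(adaptive)),
            class = "quadrature_rule")
}

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive per-replicate seed substreams from (master_seed, scenario
# id, replicate index) so that replicates are reproducible independently of
# execution order or parallelism.
string_hash31 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a replicate-level random seed
#'
#' Combines a master seed, a scenario identifier and a replicate index into
#' a single 31-bit seed. The mapping is a fixed deterministic hash, so any
#' replicate can be regenerated in isolation (e.g. under parallel
#' execution) without consuming the random stream of other replicates.
#'
#' @param master_seed Integer master seed.
#' @param scenario_id Character scenario identifier.
#' @param replicate Integer replicate index (>= 0).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
replicate_seed <- function(master_seed, scenario_id, replicate) {
  h <- string_hash31(paste(scenario_id, collapse = "|"))
  s <- (as.double(master_seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h * 69621 + as.double(replicate) * 16807) %% 2147483647)
}

# Lower-triangular Cholesky-like factor that tolerates positive
# SEMI-definite matrices (zero-variance blocks arise from degenerate
# fixtures and near-1 within-pair correlations).
psd_chol <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals))
}
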