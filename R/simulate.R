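# Correlated-outcome generators matching the marginal model and working
# correlation exactly: conditional linear family (CLF) for binary outcomes,
# multivariate normal for continuous outcomes.

# CLF coefficients are precomputed once per (mu, R): b_m solves
# Var(Y_{<m}) b = cov(Y_{<m}, Y_m), so the conditional success probability is
# lambda_m = mu_m + b' (y_{<m} - mu_{<m}).
clf_prepare <- function(mu, R) {
  n <- length(mu)
  v <- mu * (1 - mu)
  if (any(mu <= 0 | mu >= 1)) abort("CLF means must lie strictly in (0, 1).")
  Sigma <- sqrt(v) * t(sqrt(v) * R)
  coefs <- vector("list", n)
  for (m in 2:n) {
    coefs[[m]] <- drop(solve(Sigma[1:(m - 1), 1:(m - 1), drop = FALSE],
                             Sigma[1:(m - 1), m]))
  }
  list(mu = mu, coefs = coefs, n = n)
}

clf_draw <- function(prep, n_rep = 1) {
  # vectorized across replicates: Y is n_rep x n
  n <- prep$n
  mu <- prep$mu
  Y <- matrix(0L, n_rep, n)
  Y[, 1] <- as.integer(runif(n_rep) < mu[1])
  for (m in 2:n) {
    dev <- Y[, 1:(m - 1), drop = FALSE] - rep(mu[1:(m - 1)], each = n_rep)
    lambda <- mu[m] + drop(dev %*% prep$coefs[[m]])
    bad <- lambda < -1e-10 | lambda > 1 + 1e-10
    if (any(bad)) {
      abort(sprintf(
        "CLF conditional probability %.4f outside [0, 1] at record %d: the mean/correlation combination is not CLF-compatible.",
        lambda[which(bad)[1]], m
      ))
    }
    lambda <- pmin(pmax(lambda, 0), 1)
    Y[, m] <- as.integer(runif(n_rep) < lambda)
  }
  Y
}

#' Correlated binary outcomes by the conditional linear family method
#'
#' Sequentially generates binary records whose conditional success
#' probability is the linear-family expression
#' `lambda_m = mu_m + cov(Y_m, Y_<m)' Var(Y_<m)^{-1} (y_<m - mu_<m)`, with
#' covariances implied by the marginal means and the target correlation
#' matrix (`cov_ab = r_ab * sqrt(v_a v_b)`). Realized marginal means and all
#' pairwise correlations match the targets exactly in expectation. A
#' conditional probability outside `[0, 1]` aborts with the offending record
#' (the combination is not CLF-compatible) rather than clipping, which would
#' silently bias the correlations.
#'
#' @param mu Marginal mean vector, strictly inside (0, 1).
#' @param R Target correlation matrix.
#' @param n_rep Number of independent replicate vectors to draw.
#' @return An integer matrix of dimension `n_rep x length(mu)` (one row per
#'   replicate).
#' @examples
#' set.seed(1)
#' y <- generate_binary_clf(rep(0.5, 4), diag(4), n_rep = 10)
#' @export
generate_binary_clf <- function(mu, R, n_rep = 1) {
  stopifnot(length(mu) == nrow(R), nrow(R) == ncol(R))
  clf_draw(clf_prepare(mu, R), n_rep)
}

#' Correlated continuous outcomes from the multivariate normal
#'
#' Draws from a multivariate normal with mean `mu` and covariance `phi * R`
#' via Cholesky factorization.
#'
#' @param mu Mean vector.
#' @param R Correlation matrix (positive definite).
#' @param phi Total variance (dispersion).
#' @param n_rep Number of replicate vectors.
#' @return Numeric matrix `n_rep x length(mu)`.
#' @export
generate_continuous_mvn <- function(mu, R, phi = 1, n_rep = 1) {
  stopifnot(length(mu) == nrow(R))
  L <- tryCatch(chol(phi * R), error = function(e) {
    abort("Covariance factorization failed: correlation matrix is not positive definite.")
  })
  Z <- matrix(rnorm(n_rep * length(mu)), n_rep)
  sweep(Z %*% L, 2, mu, "+")
}

#' Simulate a complete stepped wedge trial dataset
#'
#' Generates one long-format dataset under the marginal mean model and
#' working correlation structure: per-cluster outcome vectors are drawn
#' independently across clusters (binary via the conditional linear family,
#' continuous via the multivariate normal), with exactly the means and
#' intracluster correlations the fast power engine assumes.
#'
#' @param design An [sw_design()].
#' @param model A [mean_model()] (its `theta` are the generating values).
#' @param corr A [corr_structure()] (generating correlation parameters).
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(design, model, corr, seed)`.
#' @return A tibble with columns `cluster`, `sequence`, `j`, `t`, `k`, `u`,
#'   `y`, ordered period-major within cluster.
#' @examples
#' simulate_sw_trial(
#'   connect_home_design(6),
#'   mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.2),
#'   corr_structure("EX", alpha0 = 0.03), seed = 42
#' )
#' @export
simulate_sw_trial <- function(design, model, corr, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fc <- feasibility_check(corr, design)
  if (!fc$feasible) {
    abort(sprintf(
      "Infeasible correlation structure on this design (min eigenvalue %.2e).",
      fc$min_eigenvalue
    ))
  }
  gens <- trial_generators(design, model, corr)
  out <- vector("list", length(gens$cluster_seq))
  for (i in seq_along(gens$cluster_seq)) {
    s <- gens$cluster_seq[i]
    y <- drop(gens$draw(s, 1))
    out[[i]] <- dplyr::mutate(gens$layout[[s]], cluster = i, sequence = s,
                              y = y, .before = 1)
  }
  dplyr::bind_rows(out)
}

# per-sequence generator closures shared by simulate_sw_trial and the
# simulation harness (prepared once, drawn many times)
trial_generators <- function(design, model, corr) {
  S <- design$n_sequences
  layouts <- vector("list", S)
  preps <- vector("list", S)
  for (s in seq_len(S)) {
    cd <- cluster_design(design, s, model$effect_model, model$q)
    md <- mean_and_derivative(cd$X, model)
    R <- sw_correlation(corr, cd$t_obs, design$cluster_period_size,
                        design$design_type)
    layouts[[s]] <- cd$layout
    preps[[s]] <- if (model$family == "binomial") {
      clf_prepare(md$mu, R)
    } else {
      list(mu = md$mu, L = chol(model$phi * R))
    }
  }
  draw <- function(s, n_rep) {
    if (model$family == "binomial") {
      clf_draw(preps[[s]], n_rep)
    } else {
      pr <- preps[[s]]
      Z <- matrix(rnorm(n_rep * length(pr$mu)), n_rep)
      sweep(Z %*% pr$L, 2, pr$mu, "+")
    }
  }
  cluster_seq <- rep(seq_len(S), times = design$clusters_per_sequence)
  list(draw = draw, layout = layouts, cluster_seq = cluster_seq)
}
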