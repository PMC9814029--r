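#' Reference complete-design matrix for one sequence
#'
#' Builds the `J x 3` design matrix of the reference complete design for
#' sequence `s`, with columns intercept, period effect `t - 1`, and treatment
#' term `u`. Under the average intervention effects model `u` is the 0/1
#' treatment indicator; under the incremental model the m-th intervention
#' period carries `u = m / q`, so `delta` is the effect after `q` periods on
#' treatment. Cells without data collection are assigned their
#' complete-design value (control before the crossover to intervention);
#' they are removed afterwards by the incidence matrix, so the assignment
#' only fixes the reference layout.
#'
#' @param design An [sw_design()].
#' @param s Sequence index.
#' @param effect_model `"average"` or `"incremental"`.
#' @param q Scaling constant for the incremental model (`u = m/q` at the m-th
#'   intervention period).
#' @param period_effects `"linear"` (column `t - 1`) or `"categorical"`
#'   (period indicator columns after the intercept).
#' @return Numeric matrix with `J` rows.
#' @export
reference_design_matrix <- function(design, s,
                                    effect_model = c("average", "incremental"),
                                    q = 10,
                                    period_effects = c("linear", "categorical")) {
  effect_model <- match.arg(effect_model)
  period_effects <- match.arg(period_effects)
  J <- design$n_periods
  t <- seq_len(J)
  u <- if (effect_model == "average") {
    as.numeric(t >= design$q0[s])
  } else {
    if (q <= 0) abort("`q` must be positive for the incremental model.")
    pmax(0, t - design$q0[s] + 1) / q
  }
  time_cols <- if (period_effects == "linear") {
    cbind(period = t - 1)
  } else {
    # period-1 reference cell coding
    m <- matrix(0, J, J - 1)
    m[cbind(2:J, 1:(J - 1))] <- 1
    colnames(m) <- paste0("period", 2:J)
    m
  }
  cbind(intercept = 1, time_cols, treatment = u)
}

#' Restrict a complete-design matrix to the observed periods
#'
#' Applies the incidence matrix: `X_inc = K %*% X_complete`, keeping the rows
#' at observed calendar periods in calendar order.
#'
#' @param K Incidence matrix from [incidence_matrix()].
#' @param X Complete-design per-period matrix (`J` rows).
#' @return Matrix with `nrow(K)` rows.
#' @export
incomplete_design_matrix <- function(K, X) {
  if (ncol(K) != nrow(X)) {
    abort(sprintf("Dimension mismatch: K has %d columns but X has %d rows.",
                  ncol(K), nrow(X)))
  }
  K %*% X
}

#' Expand a per-period matrix to individual-level rows
#'
#' Kronecker expansion `X %x% 1_N`: each period row is replicated for the `N`
#' individuals observed in that cluster-period, preserving the period-major,
#' individual-minor record ordering used throughout the package.
#'
#' @param X Per-period matrix.
#' @param N Cluster-period size.
#' @return Matrix with `N * nrow(X)` rows.
#' @export
expand_to_individuals <- function(X, N) {
  stopifnot(N >= 1)
  X[rep(seq_len(nrow(X)), each = N), , drop = FALSE]
}

#' Individual-level design matrix and record layout for one sequence
#'
#' End-to-end construction for clusters in sequence `s`: reference
#' complete-design matrix, incidence-matrix restriction to observed periods,
#' and Kronecker expansion to individuals. Also returns the record metadata
#' (observed-period index `j`, calendar period `t`, individual `k`) that
#' correlation models and simulators consume.
#'
#' @inheritParams reference_design_matrix
#' @return List with `X` (individual-level design matrix), `layout` (tibble
#'   with columns `j`, `t`, `k`, `u`), and `t_obs` (observed calendar periods).
#' @export
cluster_design <- function(design, s,
                           effect_model = c("average", "incremental"),
                           q = 10,
                           period_effects = c("linear", "categorical")) {
  effect_model <- match.arg(effect_model)
  period_effects <- match.arg(period_effects)
  cm <- dp_cm(design)$cm
  K <- incidence_matrix(cm[s, ])
  Xc <- reference_design_matrix(design, s, effect_model, q, period_effects)
  Xinc <- incomplete_design_matrix(K, Xc)
  N <- design$cluster_period_size
  X <- expand_to_individuals(Xinc, N)
  t_obs <- observed_periods(design, s)
  P <- length(t_obs)
  layout <- tibble(
    j = rep(seq_len(P), each = N),
    t = rep(t_obs, each = N),
    k = rep(seq_len(N), P),
    u = X[, ncol(X)]
  )
  list(X = X, layout = layout, t_obs = t_obs)
}
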