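# shared fixtures: study parameter sets and small reference builders

binary_model <- function(delta = -1.2, effect_model = "average", q = 10) {
  mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = delta,
             effect_model = effect_model, q = q)
}

continuous_model <- function(delta = 0.5, ...) {
  mean_model("gaussian", beta0 = 2, beta1 = -0.05, delta = delta, phi = 1, ...)
}

study_corr <- function(structure) {
  switch(structure,
    EX = corr_structure("EX", alpha0 = 0.03),
    NE = corr_structure("NE", alpha0 = 0.03, alpha1 = 0.015),
    ED = corr_structure("ED", alpha0 = 0.03, rho = 0.8),
    BE = corr_structure("BE", alpha0 = 0.03, alpha1 = 0.015, alpha2 = 0.2),
    PD = corr_structure("PD", alpha0 = 0.03, rho = 0.7)
  )
}

# dense GLS covariance oracle: assemble block-diagonal V across all clusters
# and invert (X' V^-1 X)^-1 brute force, independent of the per-sequence path
gls_covariance_oracle <- function(design, model, corr) {
  Xs <- list()
  Vs <- list()
  for (s in seq_len(design$n_sequences)) {
    for (m in seq_len(design$clusters_per_sequence[s])) {
      cd <- cluster_design(design, s, model$effect_model, model$q)
      md <- mean_and_derivative(cd$X, model)
      R <- sw_correlation(corr, cd$t_obs, design$cluster_period_size,
                          design$design_type)
      Xs <- c(Xs, list(md$D))
      Vs <- c(Vs, list(diag(sqrt(md$a)) %*% R %*% diag(sqrt(md$a))))
    }
  }
  n <- vapply(Vs, nrow, 0L)
  V <- matrix(0, sum(n), sum(n))
  at <- 0
  for (i in seq_along(Vs)) {
    ix <- at + seq_len(n[i])
    V[ix, ix] <- Vs[[i]]
    at <- at + n[i]
  }
  X <- do.call(rbind, Xs)
  solve(t(X) %*% solve(V) %*% X)
}
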