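test_that("working-independence continuous GEE collapses to least squares", {
  d <- connect_home_design(6)
  m <- continuous_model(0.5)
  dat <- simulate_sw_trial(d, m, study_corr("EX"), seed = 101)
  fit <- sw_gee(dat, m, corr_structure("EX", alpha0 = 0),
                control = list(fix_par = c(alpha0 = 0)))
  X <- cbind(1, dat$t - 1, dat$u)
  ols <- drop(solve(crossprod(X), crossprod(X, dat$y)))
  expect_true(fit$converged)
  expect_equal(unname(fit$theta), ols, tolerance = 1e-8)
  # dispersion is the moment estimate at the fitted coefficients
  rss <- sum((dat$y - X %*% ols)^2)
  expect_equal(fit$phi, rss / (nrow(dat) - 3), tolerance = 1e-6)
})

test_that("identity-link GEE with known correlation matches closed-form GLS", {
  d <- connect_home_design(6)
  m <- continuous_model(0.5)
  ne <- study_corr("NE")
  dat <- simulate_sw_trial(d, m, ne, seed = 55)
  fit <- sw_gee(dat, m, ne,
                control = list(fix_par = c(alpha0 = 0.03, alpha1 = 0.015)))
  # dense GLS with the same (fixed) working correlation
  blocks <- lapply(split(dat, dat$cluster), function(cl) {
    R <- sw_correlation(ne, unique(cl$t), d$cluster_period_size,
                        "cross-sectional")
    X <- cbind(1, cl$t - 1, cl$u)
    list(XtVX = crossprod(X, solve(R, X)), XtVy = crossprod(X, solve(R, cl$y)))
  })
  gls <- drop(solve(Reduce(`+`, lapply(blocks, `[[`, "XtVX")),
                    Reduce(`+`, lapply(blocks, `[[`, "XtVy"))))
  expect_equal(unname(fit$theta), gls, tolerance = 1e-8)
})

test_that("estimating equations are solved at convergence", {
  d <- connect_home_design(12)
  m <- binary_model(-1.4)
  ex <- study_corr("EX")
  dat <- simulate_sw_trial(d, m, ex, seed = 7)
  fit <- sw_gee(dat, m, ex)
  expect_true(fit$converged)
  # recompute the mean estimating function at the solution; measure it on
  # the parameter scale (one further scoring step must move theta by ~0)
  U <- c(0, 0, 0)
  Sig1 <- matrix(0, 3, 3)
  for (cl in split(dat, dat$cluster)) {
    X <- cbind(1, cl$t - 1, cl$u)
    eta <- drop(X %*% fit$theta)
    mu <- plogis(eta)
    D <- (mu * (1 - mu)) * X
    R <- sw_correlation(corr_structure("EX", alpha0 = unname(fit$alpha["alpha0"])),
                        unique(cl$t), d$cluster_period_size, "cross-sectional")
    V <- sqrt(mu * (1 - mu)) * t(sqrt(mu * (1 - mu)) * R)
    U <- U + drop(crossprod(solve(V, D), cl$y - mu))
    Sig1 <- Sig1 + crossprod(D, solve(V, D))
  }
  expect_lt(max(abs(solve(Sig1, U))), 1e-5)
})

test_that("correlation estimates are consistent at large cluster counts", {
  # 60 clusters, strong replication: the MAEE exchangeable estimate should
  # sit within Monte Carlo error of the generating alpha0 = 0.03
  d <- connect_home_design(12)
  d$clusters_per_sequence <- rep(10L, 6)
  m <- binary_model(-1.4)
  dat <- simulate_sw_trial(d, m, study_corr("EX"), seed = 2024)
  fit <- sw_gee(dat, m, study_corr("EX"))
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$alpha["alpha0"]) - 0.03), 0.02)
})

test_that("log-link decay structures are estimated on the gamma scale", {
  d <- connect_home_design(12)
  d$clusters_per_sequence <- rep(5L, 6)
  m <- binary_model(-1.4)
  ed <- study_corr("ED")
  dat <- simulate_sw_trial(d, m, ed, seed = 31)
  fit <- sw_gee(dat, m, ed)
  expect_true(fit$converged)
  expect_named(fit$alpha, c("alpha0", "rho"))
  expect_equal(unname(exp(fit$gamma)), unname(fit$alpha))
  expect_true(all(fit$alpha > 0 & fit$alpha < 1))
})

test_that("MAEE with zeroed leverage reduces to moment estimation", {
  d <- connect_home_design(6)
  m <- binary_model(-1.2)
  ex <- study_corr("EX")
  dat <- simulate_sw_trial(d, m, ex, seed = 77)
  fit_plain <- sw_gee(dat, m, ex, control = list(maee = FALSE))
  expect_true(fit_plain$converged)
  # hand-computed moment estimator at the fitted theta: mean of pairwise
  # Pearson residual products over all within-cluster pairs
  num <- 0
  den <- 0
  for (cl in split(dat, dat$cluster)) {
    X <- cbind(1, cl$t - 1, cl$u)
    mu <- plogis(drop(X %*% fit_plain$theta))
    e <- (cl$y - mu) / sqrt(mu * (1 - mu))
    num <- num + (sum(e)^2 - sum(e^2)) / 2
    den <- den + choose(length(e), 2)
  }
  expect_equal(unname(fit_plain$alpha["alpha0"]), num / den, tolerance = 1e-4)
  # the leverage adjustment changes the estimate
  fit_adj <- sw_gee(dat, m, ex)
  expect_false(isTRUE(all.equal(fit_adj$alpha, fit_plain$alpha,
                                tolerance = 1e-10)))
})

test_that("cluster leverages satisfy the trace identity and projection limit", {
  d <- connect_home_design(6)
  m <- binary_model(-1.2)
  ex <- study_corr("EX")
  dat <- simulate_sw_trial(d, m, ex, seed = 5)
  fit <- sw_gee(dat, m, ex)
  # rebuild per-cluster leverage at the fit and sum traces
  Sig1 <- matrix(0, 3, 3)
  parts <- lapply(split(dat, dat$cluster), function(cl) {
    X <- cbind(1, cl$t - 1, cl$u)
    mu <- plogis(drop(X %*% fit$theta))
    D <- (mu * (1 - mu)) * X
    R <- sw_correlation(corr_structure("EX", alpha0 = unname(fit$alpha["alpha0"])),
                        unique(cl$t), d$cluster_period_size, "cross-sectional")
    V <- sqrt(mu * (1 - mu)) * t(sqrt(mu * (1 - mu)) * R)
    list(D = D, V = V)
  })
  for (p_ in parts) Sig1 <- Sig1 + crossprod(p_$D, solve(p_$V, p_$D))
  Sig1_inv <- solve(Sig1)
  traces <- vapply(parts, function(p_) {
    sum(diag(leverage(p_$D, p_$V, Sig1_inv)))
  }, 0)
  expect_equal(sum(traces), 3, tolerance = 1e-8)
  # the Fay-Graubard inflation diagonal lives in (0, 1) on fitted data
  for (p_ in parts) {
    q <- diag(crossprod(p_$D, solve(p_$V, p_$D)) %*% Sig1_inv)
    expect_true(all(q > 0 & q < 1))
  }

  # single-cluster saturated case: H is a projection in the V-inner product
  p1 <- parts[[1]]
  H <- leverage(p1$D, p1$V, solve(crossprod(p1$D, solve(p1$V, p1$D))))
  expect_equal(H %*% H, H, tolerance = 1e-8)
})

test_that("matrix inverse square roots satisfy their defining identity", {
  expect_equal(matrix_sqrt_inv(diag(3)), diag(3))
  Dm <- diag(c(4, 9, 16))
  expect_equal(matrix_sqrt_inv(Dm), diag(1 / c(2, 3, 4)))
  # a non-symmetric matrix with positive real spectrum (SPD conjugated)
  set.seed(9)
  A <- crossprod(matrix(rnorm(16), 4))
  P <- matrix(rnorm(16), 4)
  M <- solve(P) %*% (A + diag(4)) %*% P
  S <- matrix_sqrt_inv(M)
  expect_equal(S %*% S, solve(M), tolerance = 1e-8)
  expect_error(matrix_sqrt_inv(-diag(2)), "eigenvalues")
})

test_that("sandwich corrections are ordered on the intervention-effect variance", {
  d <- connect_home_design(6)
  m <- binary_model(-1.2)
  for (seed in c(1, 2, 3, 4, 5)) {
    dat <- simulate_sw_trial(d, m, study_corr("EX"), seed = seed)
    fit <- sw_gee(dat, m, study_corr("EX"))
    if (!fit$converged) next
    v <- vapply(c("BC0", "BC1", "BC2"), function(nm) fit$vcov[[nm]][3, 3], 0)
    expect_true(v["BC0"] <= v["BC1"] + 1e-12)
    expect_true(v["BC1"] <= v["BC2"] + 1e-12)
    # all five estimates symmetric with positive diagonals
    for (nm in names(fit$vcov)) {
      expect_equal(fit$vcov[[nm]], t(fit$vcov[[nm]]))
      expect_true(all(diag(fit$vcov[[nm]]) > 0))
    }
  }
})

test_that("Wald tests use the requested reference distribution", {
  d <- connect_home_design(12)
  m <- binary_model(-1.4)
  dat <- simulate_sw_trial(d, m, study_corr("EX"), seed = 12)
  fit <- sw_gee(dat, m, study_corr("EX"))
  expect_true(fit$converged)
  wt <- wald_test(fit, "BC1", "t")
  wz <- wald_test(fit, "BC1", "z")
  expect_equal(wt$df, 9)
  expect_true(is.na(wz$df))
  expect_equal(wt$statistic, wz$statistic)
  # t reference is heavier-tailed, so its p-value is larger
  expect_gt(wt$p_value, wz$p_value)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "period", "treatment"))
  expect_equal(glance(fit)$converged, TRUE)
})
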