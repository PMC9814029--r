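# Simulation study orchestration: empirical size/power of the GEE/MAEE
# Wald tests per variance estimator, compared against fast-GEE predicted
# power.

#' Monte Carlo acceptance bands for empirical size and power
#'
#' Recomputes the binomial-sampling-error bands used to judge empirical
#' rates, from the nominal proportion and replicate count rather than as
#' hard-coded constants. `size_band()` is the normal-approximation 95%
#' interval around the nominal level; `power_margin()` is the largest
#' deviation of the exact (Clopper-Pearson) 95% binomial confidence interval
#' from the reference power.
#'
#' @param p Nominal level (size) or reference power.
#' @param reps Number of simulation replicates.
#' @return `size_band()`: length-2 vector; `power_margin()`: scalar margin.
#' @examples
#' round(size_band(0.05, 2000), 3) # c(0.040, 0.060)
#' round(power_margin(0.8, 1000), 3) # 0.026
#' @export
size_band <- function(p = 0.05, reps = 2000) {
  hw <- qnorm(0.975) * sqrt(p * (1 - p) / reps)
  c(lower = p - hw, upper = p + hw)
}

#' @rdname size_band
#' @export
power_margin <- function(p = 0.8, reps = 1000) {
  ci <- binom.test(round(p * reps), reps)$conf.int
  max(abs(ci - p))
}

#' Run one simulation scenario
#'
#' Generates `reps` trial replicates under the specified design, marginal
#' mean model and correlation structure, fits each by GEE/MAEE, applies the
#' two-sided Wald tests (t and z) under the five variance estimators, and
#' aggregates rejection rates over the converged replicates. Scenarios with
#' `delta = 0` estimate empirical type I error; otherwise empirical power,
#' which is compared to the fast-GEE predicted power.
#'
#' Replicates use per-replicate seed substreams derived from `seed`, so
#' results are reproducible and insensitive to scheduling order.
#'
#' @param design An [sw_design()].
#' @param model A [mean_model()] (generating and analysis model).
#' @param corr A [corr_structure()] (generating and working structure).
#' @param reps Number of replicates (1000 for power, 2000 for size studies).
#' @param seed Master seed.
#' @param tests Character subset of `c("t", "z")`.
#' @param estimators Character subset of the five variance estimators.
#' @param alpha Nominal two-sided level.
#' @param control Passed to the GEE/MAEE fitter.
#' @return An object of class `sw_scenario_result`: a list with `rates` (a
#'   tibble with one row per test x estimator), `convergence_rate`,
#'   `n_converged`, `predicted` (the [sw_power()] result) and the
#'   configuration.
#' @examples
#' run_scenario(
#'   connect_home_design(6),
#'   mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.4),
#'   corr_structure("EX", alpha0 = 0.03),
#'   reps = 5, seed = 1
#' )
#' @export
run_scenario <- function(design, model, corr, reps = 1000, seed = 1,
                         tests = c("t", "z"),
                         estimators = c("MB", "BC0", "BC1", "BC2", "BC3"),
                         alpha = 0.05, control = list()) {
  stopifnot(reps >= 1)
  tests <- match.arg(tests, c("t", "z"), several.ok = TRUE)
  estimators <- match.arg(estimators, c("MB", "BC0", "BC1", "BC2", "BC3"),
                          several.ok = TRUE)
  fc <- feasibility_check(corr, design)
  if (!fc$feasible) {
    abort(sprintf("Infeasible scenario: min correlation eigenvalue %.2e.",
                  fc$min_eigenvalue))
  }
  predicted <- sw_power(design, model, corr, alpha)
  gens <- trial_generators(design, model, corr)
  I <- length(gens$cluster_seq)
  df <- I - 3
  tcrit <- qt(1 - alpha / 2, df)
  zcrit <- qnorm(1 - alpha / 2)

  # clusters in the fitter's per-cluster representation, layout fixed
  base_clusters <- lapply(seq_len(I), function(i) {
    s <- gens$cluster_seq[i]
    lay <- gens$layout[[s]]
    list(X = cbind(intercept = 1, period = lay$t - 1, treatment = lay$u),
         y = NULL, layout = lay, t_obs = unique(lay$t))
  })

  n_cells <- length(tests) * length(estimators)
  reject <- matrix(0, length(estimators), length(tests),
                   dimnames = list(estimators, tests))
  n_conv <- 0L
  for (r in seq_len(reps)) {
    set.seed((seed + 77761 * r) %% 2147483629L)
    clusters <- base_clusters
    for (i in seq_len(I)) {
      clusters[[i]]$y <- drop(gens$draw(gens$cluster_seq[i], 1))
    }
    fit <- gee_core(clusters, model, corr, design$design_type, control)
    if (!fit$converged || is.null(fit$vcov)) next
    n_conv <- n_conv + 1L
    dhat <- unname(fit$theta[fit$p])
    for (v in estimators) {
      se <- sqrt(fit$vcov[[v]][fit$p, fit$p])
      stat <- abs(dhat / se)
      if ("t" %in% tests && stat > tcrit) reject[v, "t"] <- reject[v, "t"] + 1
      if ("z" %in% tests && stat > zcrit) reject[v, "z"] <- reject[v, "z"] + 1
    }
  }
  if (n_conv < reps / 2) {
    abort(sprintf(
      "Scenario aborted: only %d of %d replicates converged.", n_conv, reps))
  }
  rates <- tidyr::expand_grid(test = tests, variance = estimators)
  rates$rejection_rate <- purrr::map2_dbl(
    rates$test, rates$variance, function(tt, vv) reject[vv, tt] / n_conv)
  delta <- unname(model$theta["delta"])
  rates$kind <- if (delta == 0) "size" else "power"
  rates$predicted <- dplyr::if_else(
    rates$test == "t", unname(predicted$power_t), unname(predicted$power_z))
  structure(
    list(
      rates = rates, convergence_rate = n_conv / reps, n_converged = n_conv,
      reps = reps, seed = seed, alpha = alpha, delta = delta,
      predicted = predicted, design = design, model = model, corr = corr
    ),
    class = "sw_scenario_result"
  )
}

#' @export
print.sw_scenario_result <- function(x, ...) {
  cat(sprintf(
    "Scenario (%s, delta = %g): %d/%d replicates converged (%.1f%%)\n",
    x$corr$structure, x$delta, x$n_converged, x$reps,
    100 * x$convergence_rate
  ))
  print(as_tibble(x$rates))
  invisible(x)
}

#' @method tidy sw_scenario_result
#' @export
tidy.sw_scenario_result <- function(x, ...) {
  dplyr::mutate(
    as_tibble(x$rates),
    structure = x$corr$structure, delta = x$delta,
    n_clusters = n_clusters(x$design),
    convergence_rate = x$convergence_rate, reps = x$reps
  )
}

#' Compare empirical power to fast-GEE predicted power
#'
#' For a power scenario (`delta != 0`), tabulates simulated minus predicted
#' power per test and variance estimator, flagging differences inside the
#' Monte Carlo margin recomputed from the predicted power and replicate
#' count via [power_margin()].
#'
#' @param result An [run_scenario()] result.
#' @return A tibble with `difference` and `within_band` columns.
#' @export
compare_to_predicted <- function(result) {
  if (result$delta == 0) {
    abort("Comparison to predicted power requires a power scenario (delta != 0).")
  }
  rates <- as_tibble(result$rates)
  rates$difference <- rates$rejection_rate - rates$predicted
  rates$margin <- purrr::map_dbl(rates$predicted, power_margin,
                                 reps = result$reps)
  rates$within_band <- abs(rates$difference) <= rates$margin
  rates
}

#' Render a grid of scenario results as one table
#'
#' Binds tidied scenario results (rows = clusters x effect size x structure,
#' columns per test/estimator) into a single publication-style tibble.
#'
#' @param results List of [run_scenario()] results.
#' @return A tibble in long format; pivot wider for a compact layout.
#' @export
scenario_table <- function(results) {
  dplyr::bind_rows(lapply(results, tidy))
}
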