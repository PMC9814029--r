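#' Model-based covariance of the GEE estimator
#'
#' Accumulates the inverse Fisher-type information
#' `solve(sum_i t(D_i) V_i^{-1} D_i)` over clusters, where
#' `V_i = A_i^{1/2} R_i A_i^{1/2}` is the working covariance. All clusters in
#' a sequence share the same design matrix and correlation, so one
#' representative cluster per sequence is computed and weighted by `m_s`. The
#' (3,3) element is the model-based variance of the intervention-effect
#' estimator that drives analytic power.
#'
#' @param design An [sw_design()].
#' @param model A [mean_model()].
#' @param corr A [corr_structure()].
#' @return Symmetric positive-definite matrix (3 x 3 for linear period
#'   effects).
#' @export
model_based_covariance <- function(design, model, corr) {
  Sig1 <- NULL
  for (s in seq_len(design$n_sequences)) {
    cd <- cluster_design(design, s, model$effect_model, model$q)
    md <- mean_and_derivative(cd$X, model)
    R <- sw_correlation(corr, cd$t_obs, design$cluster_period_size,
                        design$design_type)
    V <- sqrt(md$a) * t(sqrt(md$a) * R)
    contrib <- design$clusters_per_sequence[s] *
      crossprod(md$D, solve(V, md$D))
    Sig1 <- if (is.null(Sig1)) contrib else Sig1 + contrib
  }
  out <- tryCatch(solve(Sig1), error = function(e) {
    abort("Singular information matrix: the design has no treatment variation or collinear terms.")
  })
  dimnames(out) <- list(colnames(Sig1), colnames(Sig1))
  out
}

#' Analytic power formulas for the intervention-effect Wald test
#'
#' `power_z()` evaluates `pnorm(qnorm(alpha/2) + abs(delta)/se)`, the
#' normal-approximation power of the two-sided Wald z-test; `power_t()`
#' evaluates the small-sample version `pt(qt(alpha/2, df) + abs(delta)/se,
#' df)` with `df = I - p` cluster degrees of freedom (central t shifted by
#' the standardized effect).
#'
#' @param var_delta Model-based variance of the intervention-effect estimator.
#' @param delta Intervention effect on the link scale.
#' @param alpha Nominal two-sided type I error rate.
#' @param I Number of clusters.
#' @param p Number of marginal mean parameters (3 for linear period effects).
#' @return Power as a probability.
#' @export
power_z <- function(var_delta, delta, alpha = 0.05) {
  stopifnot(var_delta > 0)
  pnorm(qnorm(alpha / 2) + abs(delta) / sqrt(var_delta))
}

#' @rdname power_z
#' @export
power_t <- function(var_delta, delta, I, p = 3, alpha = 0.05) {
  stopifnot(var_delta > 0)
  df <- I - p
  if (df < 1) abort("Non-positive degrees of freedom: need more clusters than mean parameters.")
  pt(qt(alpha / 2, df) + abs(delta) / sqrt(var_delta), df)
}

#' Predicted (fast GEE) power for a stepped wedge design
#'
#' End-to-end analytic power: builds the per-sequence design matrices and
#' working correlation, computes the model-based covariance of the GEE
#' estimator, and evaluates the z- and t-test power formulas for the
#' intervention effect. No simulation is involved.
#'
#' @param design An [sw_design()].
#' @param model A [mean_model()].
#' @param corr A [corr_structure()].
#' @param alpha Nominal two-sided type I error rate.
#' @return An object of class `sw_power` with elements `var_delta`,
#'   `se_delta`, `power_z`, `power_t`, `df`, `alpha`, and the inputs.
#' @examples
#' sw_power(
#'   connect_home_design(6),
#'   mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.2),
#'   corr_structure("EX", alpha0 = 0.03)
#' )
#' @export
sw_power <- function(design, model, corr, alpha = 0.05) {
  cov_mb <- model_based_covariance(design, model, corr)
  p <- nrow(cov_mb)
  vd <- cov_mb[p, p]
  I <- n_clusters(design)
  structure(
    list(
      var_delta = vd, se_delta = sqrt(vd),
      power_z = power_z(vd, model$theta["delta"], alpha),
      power_t = power_t(vd, model$theta["delta"], I, p, alpha),
      df = I - p, alpha = alpha, n_clusters = I,
      covariance = cov_mb, design = design, model = model, corr = corr
    ),
    class = "sw_power"
  )
}

#' @export
print.sw_power <- function(x, ...) {
  cat(sprintf(
    "Fast GEE power: se(delta) = %.4f, power (z) = %.3f, power (t, df = %d) = %.3f\n",
    x$se_delta, x$power_z, x$df, x$power_t
  ))
  invisible(x)
}

#' @method tidy sw_power
#' @export
tidy.sw_power <- function(x, ...) {
  tibble(
    test = c("z", "t"),
    power = c(unname(x$power_z), unname(x$power_t)),
    se_delta = x$se_delta,
    df = c(NA_integer_, x$df),
    alpha = x$alpha
  )
}

#' @method glance sw_power
#' @export
glance.sw_power <- function(x, ...) {
  tibble(
    n_clusters = x$n_clusters,
    n_periods = x$design$n_periods,
    cluster_period_size = x$design$cluster_period_size,
    structure = x$corr$structure,
    effect_model = x$model$effect_model,
    delta = unname(x$model$theta["delta"]),
    var_delta = unname(x$var_delta)
  )
}

#' Predicted power over a grid of scenarios
#'
#' Tidy wrapper around [sw_power()]: takes a data frame of scenarios and
#' returns it with power columns appended, so scenario grids pipe directly
#' into summaries and plots. Recognized columns (all optional, with
#' defaults): `clusters`, `cluster_period_size`, `family`, `beta0`, `beta1`,
#' `delta`, `effect_model`, `q`, `phi`, `structure`, `alpha0`, `alpha1`,
#' `alpha2`, `rho`, `alpha`. Correlation parameters default to the study
#' values `alpha0 = 0.03`, `alpha1 = 0.015`, `alpha2 = 0.2`, and
#' `rho = 0.8` (ED) or `0.7` (PD).
#'
#' @param scenarios A data frame, one row per scenario.
#' @param design_fn Function mapping `(clusters, cluster_period_size,
#'   design_type)` to an [sw_design()]; defaults to [connect_home_design()].
#' @return The input as a tibble with `power_z`, `power_t`, `se_delta`, `df`
#'   columns appended.
#' @examples
#' tibble::tibble(delta = c(-1.2, -1.4), structure = "EX", alpha0 = 0.03) |>
#'   sw_power_grid()
#' @export
sw_power_grid <- function(scenarios, design_fn = connect_home_design) {
  scenarios <- as_tibble(scenarios)
  get <- function(row, nm, default) {
    v <- row[[nm]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) default else v
  }
  res <- purrr::pmap_dfr(scenarios, function(...) {
    row <- list(...)
    structure_tag <- get(row, "structure", "EX")
    design_type <- if (structure_tag %in% c("BE", "PD")) "closed-cohort"
                   else get(row, "design_type", "cross-sectional")
    design <- design_fn(
      clusters = get(row, "clusters", 6),
      cluster_period_size = get(row, "cluster_period_size", NULL),
      design_type = design_type
    )
    model <- mean_model(
      family = get(row, "family", "binomial"),
      beta0 = get(row, "beta0", 0.85),
      beta1 = get(row, "beta1", -0.01),
      delta = row$delta,
      effect_model = get(row, "effect_model", "average"),
      q = get(row, "q", 10),
      phi = get(row, "phi", 1)
    )
    corr <- corr_structure(
      structure_tag,
      alpha0 = get(row, "alpha0", 0.03),
      alpha1 = get(row, "alpha1", 0.015),
      alpha2 = get(row, "alpha2", 0.2),
      rho = get(row, "rho", if (structure_tag == "PD") 0.7 else 0.8)
    )
    pw <- sw_power(design, model, corr, alpha = get(row, "alpha", 0.05))
    tibble(power_z = unname(pw$power_z), power_t = unname(pw$power_t),
           se_delta = pw$se_delta, df = pw$df)
  })
  dplyr::bind_cols(scenarios, res)
}

#' Power curve over cluster-period size or number of clusters
#'
#' Evaluates predicted power along a grid of one design dimension, holding
#' the rest of the configuration fixed. Used for sample-size determination:
#' the smallest grid value reaching a target power is reported in the
#' `target` attribute and by [print()].
#'
#' @param design An [sw_design()] serving as the template.
#' @param model A [mean_model()].
#' @param corr A [corr_structure()].
#' @param cluster_period_size,clusters Exactly one of the two: integer grid
#'   to sweep.
#' @param test `"t"` or `"z"`: which power column the target search uses.
#' @param target_power Optional power level to solve for.
#' @param alpha Nominal two-sided type I error rate.
#' @return A tibble of class `sw_power_curve` with the grid column,
#'   `power_z` and `power_t`.
#' @examples
#' sw_power_curve(
#'   connect_home_design(6),
#'   mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.4),
#'   corr_structure("EX", alpha0 = 0.03),
#'   cluster_period_size = 4:9, target_power = 0.8
#' )
#' @export
sw_power_curve <- function(design, model, corr,
                           cluster_period_size = NULL, clusters = NULL,
                           test = c("t", "z"), target_power = NULL,
                           alpha = 0.05) {
  test <- match.arg(test)
  if (is.null(cluster_period_size) == is.null(clusters)) {
    abort("Supply exactly one of `cluster_period_size` or `clusters`.")
  }
  over <- if (is.null(clusters)) "cluster_period_size" else "clusters"
  grid <- if (over == "cluster_period_size") cluster_period_size else clusters
  if (length(grid) == 0) abort("Empty grid.")
  rows <- purrr::map_dfr(grid, function(g) {
    d <- design
    if (over == "cluster_period_size") {
      d$cluster_period_size <- as.integer(g)
    } else {
      if (g %% design$n_sequences != 0) {
        abort("`clusters` values must be divisible by the number of sequences.")
      }
      d$clusters_per_sequence <- rep(as.integer(g / design$n_sequences),
                                     design$n_sequences)
    }
    pw <- sw_power(d, model, corr, alpha)
    tibble(!!over := g, power_z = unname(pw$power_z),
           power_t = unname(pw$power_t), se_delta = pw$se_delta)
  })
  out <- structure(rows, class = c("sw_power_curve", class(rows)),
                   over = over, test = test)
  if (!is.null(target_power)) {
    pcol <- paste0("power_", test)
    hit <- rows[[over]][rows[[pcol]] >= target_power]
    attr(out, "target") <- list(
      power = target_power, test = test,
      value = if (length(hit)) min(hit) else NA_integer_
    )
  }
  out
}

#' @export
print.sw_power_curve <- function(x, ...) {
  NextMethod()
  tg <- attr(x, "target")
  if (!is.null(tg)) {
    if (is.na(tg$value)) {
      cat(sprintf("No grid value reaches %s-test power %.2f\n", tg$test, tg$power))
    } else {
      cat(sprintf("Smallest %s with %s-test power >= %.2f: %d\n",
                  attr(x, "over"), tg$test, tg$power, tg$value))
    }
  }
  invisible(x)
}
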