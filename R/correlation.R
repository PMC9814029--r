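#' Specify an intracluster correlation structure
#'
#' Five working correlation structures for stepped wedge trials. For
#' cross-sectional designs: exchangeable (`"EX"`, all within-cluster pairs
#' share `alpha0`), nested exchangeable (`"NE"`, within-period `alpha0`,
#' between-period `alpha1`), and exponential decay (`"ED"`, between-period
#' correlation `alpha0 * rho^|t - t'|`). For closed cohorts: block
#' exchangeable (`"BE"`, adds the intra-individual correlation `alpha2`) and
#' proportional decay (`"PD"`, intra-individual `rho^|t - t'|` and
#' between-individual `alpha0 * rho^|t - t'|`). Decay distances are measured
#' in calendar periods, so implementation gaps contribute to the decay.
#'
#' @param structure One of `"EX"`, `"NE"`, `"ED"`, `"BE"`, `"PD"`.
#' @param alpha0 Within-period intracluster correlation.
#' @param alpha1 Between-period correlation (NE, BE).
#' @param alpha2 Intra-individual correlation (BE).
#' @param rho Decay rate per calendar period (ED, PD).
#' @return An object of class `corr_structure`.
#' @examples
#' corr_structure("NE", alpha0 = 0.03, alpha1 = 0.015)
#' @export
corr_structure <- function(structure = c("EX", "NE", "ED", "BE", "PD"),
                           alpha0, alpha1 = NULL, alpha2 = NULL, rho = NULL) {
  structure <- match.arg(structure)
  need <- switch(structure,
    EX = "alpha0",
    NE = c("alpha0", "alpha1"),
    ED = c("alpha0", "rho"),
    BE = c("alpha0", "alpha1", "alpha2"),
    PD = c("alpha0", "rho")
  )
  vals <- list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2, rho = rho)
  for (nm in need) {
    if (is.null(vals[[nm]])) {
      abort(sprintf("Structure %s requires parameter `%s`.", structure, nm))
    }
    if (vals[[nm]] < 0 || vals[[nm]] >= 1) {
      abort(sprintf("`%s` must lie in [0, 1).", nm))
    }
  }
  structure(
    list(structure = structure, alpha0 = alpha0, alpha1 = alpha1,
         alpha2 = alpha2, rho = rho),
    class = "corr_structure"
  )
}

#' @export
print.corr_structure <- function(x, ...) {
  pars <- c(alpha0 = x$alpha0, alpha1 = x$alpha1, alpha2 = x$alpha2, rho = x$rho)
  pars <- pars[!is.na(pars) & !vapply(pars, is.null, TRUE)]
  cat(sprintf("<corr_structure %s: %s>\n", x$structure,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

is_cohort_structure <- function(corr) corr$structure %in% c("BE", "PD")

# scalar correlation between two records of a cluster layout
pair_correlation <- function(corr, same_period, same_individual, dt, cohort) {
  if (same_period && same_individual) return(1)
  same_k <- cohort && same_individual
  switch(corr$structure,
    EX = corr$alpha0,
    NE = if (same_period) corr$alpha0 else corr$alpha1,
    ED = if (same_period) corr$alpha0 else corr$alpha0 * corr$rho^dt,
    BE = if (same_period) corr$alpha0 else if (same_k) corr$alpha2 else corr$alpha1,
    PD = if (same_period) corr$alpha0 else if (same_k) corr$rho^dt else corr$alpha0 * corr$rho^dt
  )
}

#' Within-cluster correlation matrix on a record layout
#'
#' Builds the working correlation matrix for a cluster whose records are laid
#' out period-major (all individuals of period 1, then period 2, ...). For a
#' complete design pass all `J` calendar periods; for an incomplete design
#' pass the observed calendar periods — the result equals the principal
#' submatrix `K R_complete K'` of the complete-grid matrix at the observed
#' rows.
#'
#' @param corr A [corr_structure()].
#' @param calendar_times Calendar period of each period slot, in order.
#' @param N Individuals per period slot.
#' @param design_type `"cross-sectional"` or `"closed-cohort"`; cohort
#'   structures (BE, PD) require a closed cohort, where individual `k` is the
#'   same person in every period.
#' @return Symmetric correlation matrix of size `length(calendar_times) * N`.
#' @export
sw_correlation <- function(corr, calendar_times, N,
                           design_type = c("cross-sectional", "closed-cohort")) {
  design_type <- match.arg(design_type)
  cohort <- design_type == "closed-cohort"
  if (is_cohort_structure(corr) && !cohort) {
    abort(sprintf(
      "Structure %s models intra-individual correlation and requires a closed-cohort design.",
      corr$structure
    ))
  }
  P <- length(calendar_times)
  n <- P * N
  per <- rep(seq_len(P), each = N)
  ind <- rep(seq_len(N), P)
  t <- calendar_times[per]
  # vectorized assembly over the five case rules
  same_period <- outer(per, per, "==")
  same_ind <- outer(ind, ind, "==")
  dt <- abs(outer(t, t, "-"))
  R <- matrix(0, n, n)
  a0 <- corr$alpha0
  R[same_period] <- a0
  between <- !same_period
  R[between] <- switch(corr$structure,
    EX = a0,
    NE = corr$alpha1,
    ED = a0 * corr$rho^dt[between],
    BE = ifelse(same_ind[between], corr$alpha2, corr$alpha1),
    PD = ifelse(same_ind[between], corr$rho^dt[between],
                a0 * corr$rho^dt[between])
  )
  diag(R) <- 1
  R
}

#' Restrict a complete-grid correlation matrix to observed records
#'
#' `R_inc = K R K'` where `K` is the period-level incidence matrix expanded
#' to individual rows (Kronecker product with the `N`-identity). Equivalent
#' to taking the principal submatrix of `R` at the observed records.
#'
#' @param K Period-level incidence matrix.
#' @param R Complete-grid correlation matrix of size `ncol(K) * N`.
#' @param N Individuals per period.
#' @return Principal submatrix of `R`.
#' @export
incomplete_correlation <- function(K, R, N) {
  if (ncol(K) * N != nrow(R)) {
    abort(sprintf("Dimension mismatch: K implies %d records but R has %d rows.",
                  ncol(K) * N, nrow(R)))
  }
  KN <- K %x% diag(N)
  KN %*% R %*% t(KN)
}

#' Pairwise correlation-model covariates
#'
#' Encodes, for every unordered record pair of a cluster layout, the covariate
#' vector of the generalized linear model for the pairwise correlations. On
#' the identity link (EX/NE/BE) the covariates are the three mutually
#' exclusive indicators (same period; different period, different individual;
#' different period, same individual); on the log link (ED/PD) they are the
#' different-individual indicator and the absolute calendar-time distance,
#' so `log(rho_pair) = z0 * gamma0 + z1 * gamma1` with `alpha0 = exp(gamma0)`
#' and `rho = exp(gamma1)`.
#'
#' @param layout Data frame with one row per record, columns `j` (period
#'   index), `k` (individual) and `t` (calendar period), in record order.
#' @param link `"identity"` or `"log"`.
#' @param design_type Whether `k` indexes the same person across periods.
#' @return A tibble with columns `a`, `b` (record indices of the pair) and
#'   the covariates (`z0`, `z1`, `z2` for identity; `z0`, `z1` for log).
#' @export
pair_covariates <- function(layout, link = c("identity", "log"),
                            design_type = c("cross-sectional", "closed-cohort")) {
  link <- match.arg(link)
  design_type <- match.arg(design_type)
  cohort <- design_type == "closed-cohort"
  n <- nrow(layout)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  same_period <- layout$j[a] == layout$j[b]
  same_ind <- cohort & layout$k[a] == layout$k[b]
  dt <- abs(layout$t[a] - layout$t[b])
  if (link == "identity") {
    tibble(
      a = a, b = b,
      z0 = as.numeric(same_period),
      z1 = as.numeric(!same_period & !same_ind),
      z2 = as.numeric(!same_period & same_ind)
    )
  } else {
    tibble(a = a, b = b, z0 = as.numeric(!same_ind), z1 = dt)
  }
}

#' Positive-definiteness feasibility of a correlation structure on a design
#'
#' Checks whether the working correlation matrix implied by a structure is
#' positive definite on each sequence of a design. A non-positive-definite
#' matrix cannot generate data and signals an infeasible parameter
#' combination; for power computation only invertibility is needed, so the
#' check reports rather than raises.
#'
#' @param corr A [corr_structure()].
#' @param design An [sw_design()].
#' @param tol Minimum-eigenvalue threshold for feasibility.
#' @return A list with `feasible` (logical) and `min_eigenvalue` (over all
#'   sequences).
#' @export
feasibility_check <- function(corr, design, tol = 1e-10) {
  min_ev <- Inf
  for (s in seq_len(design$n_sequences)) {
    R <- sw_correlation(corr, observed_periods(design, s),
                        design$cluster_period_size, design$design_type)
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    min_ev <- min(min_ev, ev)
  }
  list(feasible = min_ev > tol, min_eigenvalue = min_ev)
}
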