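# GEE with matrix-adjusted estimating equations (MAEE) for intracluster
# correlations, and the five variance estimators (model-based, BC0-BC3).
#
# Internal per-cluster representation ("cluster list"): for each cluster a
# list with X (design matrix), y (response), layout (j, t, k), t_obs.
# Correlation parameters are estimated on the identity link (EX/NE/BE) or
# the log link (ED/PD, gamma = log(alpha0), log(rho)).

#' Fit a marginal model to stepped wedge trial data by GEE/MAEE
#'
#' Alternates (a) Fisher scoring for the marginal mean parameters solving
#' the standard first-order GEE, (b) a second set of estimating equations for
#' the correlation parameters with a matrix-based finite-sample bias
#' adjustment (MAEE) built from the cluster leverages, and (c) a
#' method-of-moments dispersion update for continuous outcomes. At
#' convergence the five variance estimators of the mean parameters are
#' computed: model-based, the unadjusted sandwich (BC0) and its
#' Kauermann-Carroll (BC1), Mancl-DeRouen (BC2) and Fay-Graubard (BC3)
#' finite-sample corrections.
#'
#' @param data Long-format data frame with columns `cluster`, `sequence`,
#'   `j` (observed-period index), `t` (calendar period), `k` (individual),
#'   `u` (treatment term) and `y` (outcome), ordered period-major within
#'   cluster.
#' @param model A [mean_model()]; its `theta` is ignored (used only for
#'   family/link/effect-model metadata).
#' @param corr A [corr_structure()] naming the working structure; its
#'   parameter values are ignored (estimated).
#' @param design_type `"cross-sectional"` or `"closed-cohort"`.
#' @param control List of fitting controls: `max_iter` (default 100), `tol`
#'   (max absolute parameter change, 1e-6), `zeta` (Fay-Graubard bound,
#'   0.75), `maee` (set `FALSE` to zero the leverage adjustment and recover
#'   unadjusted moment estimation of the correlations), `fix_par` (named
#'   vector of correlation parameters to hold fixed instead of estimating,
#'   e.g. `c(alpha0 = 0)` for working independence).
#' @return An object of class `sw_gee` with elements `theta`, `alpha`
#'   (named correlation estimates), `gamma` (log-link scale, decay
#'   structures), `phi`, `converged`, `n_iter`, `vcov` (list of the five
#'   3 x 3 matrices) and bookkeeping needed by [wald_test()].
#' @examples
#' d <- connect_home_design(6)
#' m <- mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.2)
#' dat <- simulate_sw_trial(d, m, corr_structure("EX", alpha0 = 0.03), seed = 1)
#' fit <- sw_gee(dat, m, corr_structure("EX", alpha0 = 0.03))
#' tidy(fit)
#' @export
sw_gee <- function(data, model, corr,
                   design_type = c("cross-sectional", "closed-cohort"),
                   control = list()) {
  design_type <- match.arg(design_type)
  if (is_cohort_structure(corr)) design_type <- "closed-cohort"
  clusters <- split_clusters(data)
  gee_core(clusters, model, corr, design_type, control)
}

split_clusters <- function(data) {
  need <- c("cluster", "j", "t", "k", "u", "y")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing columns in long-format data: ",
                 paste(miss, collapse = ", "), "."))
  }
  data <- data[order(data$cluster, data$j, data$k), ]
  lapply(split(seq_len(nrow(data)), data$cluster), function(ix) {
    d <- data[ix, ]
    X <- cbind(intercept = 1, period = d$t - 1, treatment = d$u)
    list(X = X, y = d$y, layout = d[, c("j", "t", "k")],
         t_obs = unique(d$t))
  })
}

# pair metadata for one cluster, precomputed once per distinct layout
pair_meta <- function(layout, corr, design_type) {
  link <- if (corr$structure %in% c("ED", "PD")) "log" else "identity"
  z <- pair_covariates(layout, link, design_type)
  Z <- switch(corr$structure,
    EX = matrix(1, nrow(z), 1, dimnames = list(NULL, "alpha0")),
    NE = cbind(alpha0 = z$z0, alpha1 = z$z1 + z$z2),
    BE = cbind(alpha0 = z$z0, alpha1 = z$z1, alpha2 = z$z2),
    ED = cbind(gamma0 = z$z0, gamma1 = z$z1),
    PD = cbind(gamma0 = z$z0, gamma1 = z$z1)
  )
  list(a = z$a, b = z$b, Z = Z, link = link)
}

corr_from_pairs <- function(pm, par, n) {
  # working correlation matrix from the pair model at current parameters
  rho <- if (pm$link == "identity") drop(pm$Z %*% par) else exp(drop(pm$Z %*% par))
  R <- diag(n)
  R[cbind(pm$a, pm$b)] <- rho
  R[cbind(pm$b, pm$a)] <- rho
  R
}

par_init <- function(corr) {
  switch(corr$structure,
    EX = c(alpha0 = 0.01),
    NE = c(alpha0 = 0.01, alpha1 = 0.01),
    BE = c(alpha0 = 0.01, alpha1 = 0.01, alpha2 = 0.01),
    ED = c(gamma0 = log(0.01), gamma1 = log(0.01)),
    PD = c(gamma0 = log(0.01), gamma1 = log(0.01))
  )
}

par_feasible <- function(par, link) {
  if (link == "identity") all(par > -1 & par < 1) else all(exp(par) < 1)
}

gee_core <- function(clusters, model, corr, design_type, control = list()) {
  ctl <- utils::modifyList(
    list(max_iter = 100L, tol = 1e-6, zeta = 0.75, maee = TRUE,
         fix_par = NULL), control)
  I <- length(clusters)
  p <- ncol(clusters[[1]]$X)

  # distinct layouts share pair metadata (all clusters of a sequence do)
  keys <- vapply(clusters, function(cl) paste(cl$layout$t, cl$layout$k, collapse = ","), "")
  meta_tab <- lapply(clusters[!duplicated(keys)], function(cl)
    pair_meta(cl$layout, corr, design_type))
  names(meta_tab) <- keys[!duplicated(keys)]
  pm_of <- meta_tab[keys]

  # initialize theta from independence-working GEE
  theta <- gee_independence(clusters, model, p, ctl)
  par <- if (is.null(ctl$fix_par)) par_init(corr) else ctl$fix_par
  link <- if (corr$structure %in% c("ED", "PD")) "log" else "identity"
  phi <- model$phi
  converged <- FALSE
  iter <- 0L
  boundary_failure <- FALSE

  repeat {
    iter <- iter + 1L
    # per-cluster state at current parameters
    st <- lapply(seq_len(I), function(i) {
      cl <- clusters[[i]]
      md <- mean_and_derivative(cl$X, model, theta)
      md$a <- phi * variance_function(model$family, md$mu)
      R <- corr_from_pairs(pm_of[[i]], par, nrow(cl$X))
      V <- sqrt(md$a) * t(sqrt(md$a) * R)
      list(mu = md$mu, D = md$D, a = md$a, V = V, resid = cl$y - md$mu)
    })

    # (a) Fisher scoring update for theta
    Sig1 <- matrix(0, p, p)
    score <- numeric(p)
    ViD <- vector("list", I)
    for (i in seq_len(I)) {
      ViD[[i]] <- solve(st[[i]]$V, st[[i]]$D)
      Sig1 <- Sig1 + crossprod(st[[i]]$D, ViD[[i]])
      score <- score + crossprod(ViD[[i]], st[[i]]$resid)
    }
    Sig1_inv <- solve(Sig1)
    theta_new <- theta + drop(Sig1_inv %*% score)

    # (b) MAEE update of correlation parameters
    up <- if (is.null(ctl$fix_par)) {
      maee_update(clusters, st, ViD, Sig1_inv, pm_of, par, link, phi,
                  model, ctl)
    } else {
      phi_fixed <- if (model$family == "gaussian") {
        e2 <- sum(vapply(st, function(s_i) sum(s_i$resid^2 / (s_i$a / phi)),
                         0))
        e2 / (sum(vapply(st, function(s_i) length(s_i$resid), 0L)) - p)
      } else {
        phi
      }
      list(par = par, phi = phi_fixed, boundary_failure = FALSE)
    }
    if (up$boundary_failure) {
      boundary_failure <- TRUE
      par_new <- up$par
      phi_new <- up$phi
      theta <- theta_new
      break
    }
    par_new <- up$par
    phi_new <- up$phi

    delta_par <- max(abs(theta_new - theta), abs(par_new - par),
                     abs(phi_new - phi))
    theta <- theta_new
    par <- par_new
    phi <- phi_new
    if (delta_par < ctl$tol) {
      converged <- TRUE
      break
    }
    if (iter >= ctl$max_iter) break
  }

  names(theta) <- colnames(clusters[[1]]$X)
  alpha <- if (link == "identity") {
    par
  } else {
    c(alpha0 = unname(exp(par["gamma0"])), rho = unname(exp(par["gamma1"])))
  }

  # final state and variance estimators
  st <- lapply(seq_len(I), function(i) {
    cl <- clusters[[i]]
    md <- mean_and_derivative(cl$X, model, theta)
    md$a <- phi * variance_function(model$family, md$mu)
    R <- corr_from_pairs(pm_of[[i]], par, nrow(cl$X))
    V <- sqrt(md$a) * t(sqrt(md$a) * R)
    list(mu = md$mu, D = md$D, a = md$a, V = V, resid = cl$y - md$mu)
  })
  vc <- tryCatch(
    sandwich_variances(st, zeta = ctl$zeta),
    error = function(e) NULL
  )
  if (is.null(vc)) converged <- FALSE

  structure(
    list(
      theta = theta, alpha = alpha, gamma = if (link == "log") par else NULL,
      phi = phi, converged = converged && !boundary_failure,
      boundary_failure = boundary_failure, n_iter = iter,
      n_clusters = I, p = p,
      vcov = vc, corr = corr, model = model, design_type = design_type
    ),
    class = "sw_gee"
  )
}

gee_independence <- function(clusters, model, p, ctl) {
  # working-independence GEE for initial theta (IRLS)
  X <- do.call(rbind, lapply(clusters, `[[`, "X"))
  y <- unlist(lapply(clusters, `[[`, "y"), use.names = FALSE)
  theta <- switch(model$link,
    identity = drop(solve(crossprod(X), crossprod(X, y))),
    logit = ,
    log = {
      th <- rep(0, p)
      mu0 <- mean(y)
      th[1] <- switch(model$link, logit = stats::qlogis(min(max(mu0, 0.05), 0.95)),
                      log = log(max(mu0, 0.05)))
      for (it in 1:25) {
        eta <- drop(X %*% th)
        mu <- linkinv(model$link, eta)
        w <- mu_eta(model$link, eta)^2 / variance_function(model$family, mu)
        z <- eta + (y - mu) / mu_eta(model$link, eta)
        th_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
        if (max(abs(th_new - th)) < 1e-8) {
          th <- th_new
          break
        }
        th <- th_new
      }
      th
    }
  )
  theta
}

maee_update <- function(clusters, st, ViD, Sig1_inv, pm_of, par, link, phi,
                        model, ctl) {
  I <- length(clusters)
  p <- ncol(Sig1_inv)
  # Pearson residuals and adjusted cross-products per cluster
  n_total <- 0
  press2 <- 0
  lhs <- 0
  rhs <- 0
  for (i in seq_len(I)) {
    s_i <- st[[i]]
    e <- s_i$resid / sqrt(s_i$a)
    n_total <- n_total + length(e)
    press2 <- press2 + sum(e^2)
    pm <- pm_of[[i]]
    if (ctl$maee) {
      H <- s_i$D %*% Sig1_inv %*% t(ViD[[i]])   # leverage D (sum D'V^-1 D)^-1 D'V^-1
      G <- solve(diag(nrow(H)) - H, e)
      svec <- (G[pm$a] * e[pm$b] + G[pm$b] * e[pm$a]) / 2
    } else {
      svec <- e[pm$a] * e[pm$b]
    }
    if (link == "identity") {
      lhs <- lhs + crossprod(pm$Z)
      rhs <- rhs + crossprod(pm$Z, svec)
    } else {
      sig <- exp(drop(pm$Z %*% par))
      E <- sig * pm$Z
      lhs <- lhs + crossprod(E)
      rhs <- rhs + crossprod(E, svec - sig)
    }
  }
  par_new <- if (link == "identity") {
    drop(solve(lhs, rhs))
  } else {
    par + drop(solve(lhs, rhs))
  }
  names(par_new) <- names(par)

  boundary_failure <- FALSE
  if (!par_feasible(par_new, link)) {
    # step-halve toward the previous iterate
    ok <- FALSE
    step <- par_new - par
    for (h in 1:10) {
      step <- step / 2
      cand <- par + step
      if (par_feasible(cand, link)) {
        par_new <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) boundary_failure <- TRUE
  }

  phi_new <- if (model$family == "gaussian") {
    phi * press2 / (n_total - p)
  } else {
    phi
  }
  list(par = par_new, phi = phi_new, boundary_failure = boundary_failure)
}

#' Cluster leverage matrix
#'
#' `H_i = D_i (sum_i D_i' V_i^{-1} D_i)^{-1} D_i' V_i^{-1}`, the
#' generalization of hat-matrix leverage to GEE clusters; the traces of the
#' `H_i` sum to the number of mean parameters.
#'
#' @param D Cluster derivative matrix.
#' @param V Cluster working covariance.
#' @param Sig1_inv Inverse of the accumulated information.
#' @return The `n_i x n_i` leverage matrix.
#' @export
leverage <- function(D, V, Sig1_inv) {
  D %*% Sig1_inv %*% t(solve(V, D))
}

#' Inverse matrix square root of (I - H)
#'
#' Computes `(I - H)^{-1/2}` for a (generally non-symmetric) leverage
#' complement via eigendecomposition, as required by the Kauermann-Carroll
#' sandwich correction. The spectrum must be real and positive.
#'
#' @param M The matrix `I - H`.
#' @return A matrix `S` with `S %*% S` equal to `solve(M)`.
#' @export
matrix_sqrt_inv <- function(M) {
  ev <- eigen(M)
  if (any(abs(Im(ev$values)) > 1e-8) || any(Re(ev$values) <= 0)) {
    abort("Cannot take inverse square root: (I - H) has non-positive or complex eigenvalues.")
  }
  S <- ev$vectors %*% (Re(ev$values)^(-1 / 2) * solve(ev$vectors))
  Re(S)
}

# five variance estimators from the final per-cluster state
sandwich_variances <- function(st, zeta = 0.75) {
  I <- length(st)
  p <- ncol(st[[1]]$D)
  Sig1 <- matrix(0, p, p)
  ViD <- vector("list", I)
  for (i in seq_len(I)) {
    ViD[[i]] <- solve(st[[i]]$V, st[[i]]$D)
    Sig1 <- Sig1 + crossprod(st[[i]]$D, ViD[[i]])
  }
  Sig1_inv <- solve(Sig1)
  meat0 <- meat1 <- meat2 <- meat3 <- matrix(0, p, p)
  for (i in seq_len(I)) {
    D <- st[[i]]$D
    r <- st[[i]]$resid
    g0 <- crossprod(ViD[[i]], r)                 # D' V^-1 r
    H <- D %*% Sig1_inv %*% t(ViD[[i]])
    IH <- diag(nrow(H)) - H
    B1 <- matrix_sqrt_inv(IH)
    B2r <- solve(IH, r)
    g1 <- crossprod(ViD[[i]], B1 %*% r)
    g2 <- crossprod(ViD[[i]], B2r)
    # Fay-Graubard diagonal inflation on the parameter scale
    Q <- crossprod(D, ViD[[i]]) %*% Sig1_inv     # D'V^-1 D Sigma1^-1
    Fd <- (1 - pmin(zeta, diag(Q)))^(-1 / 2)
    g3 <- Fd * g0
    meat0 <- meat0 + tcrossprod(g0)
    meat1 <- meat1 + tcrossprod(g1)
    meat2 <- meat2 + tcrossprod(g2)
    meat3 <- meat3 + tcrossprod(g3)
  }
  nm <- colnames(st[[1]]$D)
  out <- list(
    MB = Sig1_inv,
    BC0 = Sig1_inv %*% meat0 %*% Sig1_inv,
    BC1 = Sig1_inv %*% meat1 %*% Sig1_inv,
    BC2 = Sig1_inv %*% meat2 %*% Sig1_inv,
    BC3 = Sig1_inv %*% meat3 %*% Sig1_inv
  )
  lapply(out, function(m) {
    m <- (m + t(m)) / 2
    dimnames(m) <- list(nm, nm)
    m
  })
}

#' Wald test of the intervention effect
#'
#' Two-sided Wald test of no intervention effect from a fitted GEE/MAEE
#' model, using any of the five variance estimators and either the normal
#' reference or the t reference with `I - p` cluster degrees of freedom.
#'
#' @param fit An [sw_gee()] fit.
#' @param variance One of `"MB"`, `"BC0"`, `"BC1"`, `"BC2"`, `"BC3"`.
#' @param test `"t"` or `"z"`.
#' @param alpha Nominal two-sided level.
#' @return A tibble with `statistic`, `se`, `df`, `p_value`, `reject`.
#' @export
wald_test <- function(fit, variance = "BC1", test = c("t", "z"), alpha = 0.05) {
  test <- match.arg(test)
  variance <- match.arg(variance, c("MB", "BC0", "BC1", "BC2", "BC3"))
  if (is.null(fit$vcov)) abort("Fit has no variance estimates (convergence failure).")
  se <- sqrt(fit$vcov[[variance]][fit$p, fit$p])
  stat <- unname(fit$theta[fit$p]) / se
  df <- fit$n_clusters - fit$p
  pval <- if (test == "t") 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  tibble(
    variance = variance, test = test, statistic = stat, se = se,
    df = if (test == "t") df else NA_integer_,
    p_value = pval, reject = pval < alpha
  )
}

#' @export
print.sw_gee <- function(x, ...) {
  cat(sprintf("GEE/MAEE fit (%s, %s working correlation): %s in %d iterations\n",
              x$model$family, x$corr$structure,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("theta:", paste(sprintf("%s = %.4f", names(x$theta), x$theta),
                      collapse = ", "), "\n")
  cat("alpha:", paste(sprintf("%s = %.4f", names(x$alpha), x$alpha),
                      collapse = ", "), "\n")
  if (x$model$family == "gaussian") cat(sprintf("phi: %.4f\n", x$phi))
  invisible(x)
}

#' @method tidy sw_gee
#' @export
tidy.sw_gee <- function(x, variance = "BC1", conf.int = FALSE,
                        conf.level = 0.95, ...) {
  if (is.null(x$vcov)) {
    return(tibble(term = names(x$theta), estimate = unname(x$theta),
                  std.error = NA_real_, statistic = NA_real_,
                  p.value = NA_real_))
  }
  variance <- match.arg(variance, c("MB", "BC0", "BC1", "BC2", "BC3"))
  se <- sqrt(diag(x$vcov[[variance]]))
  est <- unname(x$theta)
  stat <- est / se
  df <- x$n_clusters - x$p
  out <- tibble(
    term = names(x$theta), estimate = est, std.error = unname(se),
    statistic = unname(stat), p.value = unname(2 * pt(-abs(stat), df))
  )
  if (conf.int) {
    tq <- qt(1 - (1 - conf.level) / 2, df)
    out$conf.low <- out$estimate - tq * out$std.error
    out$conf.high <- out$estimate + tq * out$std.error
  }
  out
}

#' @method glance sw_gee
#' @export
glance.sw_gee <- function(x, ...) {
  tibble(
    converged = x$converged, n_iter = x$n_iter, n_clusters = x$n_clusters,
    structure = x$corr$structure, phi = x$phi,
    !!!stats::setNames(as.list(unname(x$alpha)), names(x$alpha))
  )
}
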