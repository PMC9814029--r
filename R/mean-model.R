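#' Specify the marginal mean model
#'
#' The marginal (population-averaged) mean model links the mean response to a
#' linear period effect and the treatment term:
#' `g(mu) = beta0 + beta1 * (t - 1) + u * delta`. Under the average
#' intervention effects model `u` is the 0/1 treatment indicator and `delta`
#' the intervention effect on the link scale; under the incremental model
#' `u = m/q` at the m-th period on treatment, so `delta` is the effect after
#' `q` intervention periods.
#'
#' @param family `"binomial"` (binary outcome, variance `mu(1-mu)`, `phi = 1`),
#'   `"gaussian"` (variance function 1, dispersion `phi`), or `"poisson"`
#'   (variance `mu`).
#' @param link `"logit"`, `"identity"` or `"log"`.
#' @param beta0 Intercept (mean at calendar period 1, control, link scale).
#' @param beta1 Linear period-effect slope on the link scale.
#' @param delta Intervention effect on the link scale.
#' @param effect_model `"average"` or `"incremental"`.
#' @param q Incremental-model scaling constant (periods on treatment at which
#'   `delta` is interpreted).
#' @param phi Dispersion parameter (forced to 1 for binary outcomes).
#' @return An object of class `mean_model`.
#' @examples
#' mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.2)
#' @export
mean_model <- function(family = c("binomial", "gaussian", "poisson"),
                       link = NULL,
                       beta0, beta1, delta,
                       effect_model = c("average", "incremental"),
                       q = 10, phi = 1) {
  family <- match.arg(family)
  effect_model <- match.arg(effect_model)
  link <- link %||% switch(family, binomial = "logit",
                           gaussian = "identity", poisson = "log")
  link <- match.arg(link, c("logit", "identity", "log"))
  if (family == "binomial" && link != "logit") {
    abort("Binary outcomes are supported with the logit link.")
  }
  if (family == "binomial") phi <- 1
  if (phi <= 0) abort("`phi` must be positive.")
  if (effect_model == "incremental" && q <= 0) abort("`q` must be positive.")
  structure(
    list(family = family, link = link,
         theta = c(beta0 = beta0, beta1 = beta1, delta = delta),
         effect_model = effect_model, q = q, phi = phi),
    class = "mean_model"
  )
}

#' @export
print.mean_model <- function(x, ...) {
  cat(sprintf(
    "<mean_model %s/%s, %s effects%s: beta0 = %g, beta1 = %g, delta = %g, phi = %g>\n",
    x$family, x$link, x$effect_model,
    if (x$effect_model == "incremental") sprintf(" (q = %g)", x$q) else "",
    x$theta[1], x$theta[2], x$theta[3], x$phi
  ))
  invisible(x)
}

linkinv <- function(link, eta) {
  switch(link, logit = plogis(eta), identity = eta, log = exp(eta))
}

# derivative d mu / d eta
mu_eta <- function(link, eta) {
  switch(link,
    logit = {
      p <- plogis(eta)
      p * (1 - p)
    },
    identity = rep(1, length(eta)),
    log = exp(eta)
  )
}

variance_function <- function(family, mu) {
  switch(family,
    binomial = mu * (1 - mu),
    gaussian = rep(1, length(mu)),
    poisson = mu
  )
}

#' Marginal mean, derivative and variance components for one cluster
#'
#' Evaluates, at given mean-model parameters, the mean vector
#' `mu = g^{-1}(X theta)`, the derivative matrix `D = d mu / d theta'`, and
#' the diagonal variance matrix `A = phi * diag(v(mu))` for one cluster's
#' design matrix.
#'
#' @param X Individual-level design matrix.
#' @param model A [mean_model()].
#' @param theta Optional parameter vector overriding the model's (used during
#'   fitting).
#' @return List with `mu`, `D`, and `a` (the diagonal of `A`).
#' @export
mean_and_derivative <- function(X, model, theta = NULL) {
  theta <- theta %||% model$theta
  eta <- drop(X %*% theta)
  mu <- linkinv(model$link, eta)
  if (model$family == "binomial" && any(mu <= 0 | mu >= 1)) {
    abort("Mean outside (0, 1) for a binary outcome.")
  }
  list(
    mu = mu,
    D = mu_eta(model$link, eta) * X,
    a = model$phi * variance_function(model$family, mu)
  )
}
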