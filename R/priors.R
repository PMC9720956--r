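#' Gamma prior parameterised by mean and coefficient of variation
#'
#' The gamma distribution with shape `k` and scale `theta` has mean
#' `k * theta` and coefficient of variation `1/sqrt(k)`; inverting gives
#' `shape = 1/cv^2` and `scale = mean * cv^2`. Parameterising by (mean, cv)
#' makes a weakly informative prior easy to read: the mean pins the expected
#' scale of the parameter, the cv how strongly it is constrained.
#'
#' @param mean Prior mean (> 0), in the units of the parameter.
#' @param cv Prior coefficient of variation (> 0), dimensionless.
#' @return An object of class `"gamma_prior"`: list with `mean`, `cv`,
#'   `shape`, `scale`.
#' @examples
#' gamma_prior(log(2) / 3, 1) # shape 1: an exponential prior
#' @export
gamma_prior <- function(mean, cv) {
  stopifnot(is.finite(mean), is.finite(cv), mean > 0, cv > 0)
  structure(list(mean = mean, cv = cv, shape = 1 / cv^2, scale = mean * cv^2),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("Gamma prior: mean %.4g, CV %.4g (shape %.4g, scale %.4g)\n",
              x$mean, x$cv, x$shape, x$scale))
  invisible(x)
}

#' Default weakly informative priors for the five inferred parameters
#'
#' Independent gamma priors chosen to confine each parameter to a physically
#' plausible range: the division rate alpha around a 3 h doubling time
#' (mean ln2/3 per hour, CV 1), identical priors for the break rate beta and
#' repair rate rho (mean ln2/6, CV 2) so that neither step is favoured as
#' rate-limiting, a narrow prior on the lag tau around the known 4 h
#' metabolic-switch duration (CV 0.1), and a broad prior on the measurement
#' noise sigma (mean ln2/3, CV 2, dimensionless).
#'
#' @return An object of class `"prior_set"`: a named list of
#'   [gamma_prior()] objects for `alpha`, `beta`, `rho`, `tau`, `sigma`.
#' @examples
#' default_priors()$beta
#' @export
default_priors <- function() {
  structure(list(
    alpha = gamma_prior(log(2) / 3, 1),
    beta  = gamma_prior(log(2) / 6, 2),
    rho   = gamma_prior(log(2) / 6, 2),
    tau   = gamma_prior(4, 0.1),
    sigma = gamma_prior(log(2) / 3, 2)
  ), class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat("Independent gamma priors (mean, CV):\n")
  for (nm in names(x)) {
    cat(sprintf("  %-6s mean %.4g  CV %.4g\n", nm, x[[nm]]$mean, x[[nm]]$cv))
  }
  invisible(x)
}

#' Log prior density of a parameter vector
#'
#' Sum of independent gamma log-densities. Any nonpositive component has
#' zero prior mass, so `-Inf` is returned (not an error), which lets a
#' sampler reject such proposals gracefully.
#'
#' @param theta Named numeric vector with components `alpha`, `beta`, `rho`,
#'   `tau`, `sigma`.
#' @param priors A `"prior_set"` from [default_priors()] (or modified).
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors = default_priors()) {
  nms <- names(priors)
  th <- theta[nms]
  if (any(!is.finite(th)) || any(th <= 0)) return(-Inf)
  lp <- 0
  for (nm in nms) {
    pr <- priors[[nm]]
    lp <- lp + stats::dgamma(th[[nm]], shape = pr$shape, scale = pr$scale,
                             log = TRUE)
  }
  lp
}

#' Moment-match a gamma prior to the posterior lag-time marginal
#'
#' The lag is assumed common to all experimental conditions, so it is
#' inferred once (from a reference condition) and the resulting posterior
#' marginal is re-used, as a moment-matched gamma distribution, as the lag
#' prior for every other fit. A floor of 1e-3 on the matched CV guards
#' against degenerate (zero-variance) gammas.
#'
#' @param fit A `"dsbr_fit"` object from [fit_repair_model()].
#' @return A [gamma_prior()] with the posterior's mean and CV of `tau`.
#' @export
propagate_tau_prior <- function(fit) {
  stopifnot(inherits(fit, "dsbr_fit"))
  draws <- fit$draws[, "tau"]
  m <- mean(draws)
  cv <- stats::sd(draws) / m
  if (!is.finite(cv) || cv < 1e-3) cv <- 1e-3
  gamma_prior(m, cv)
}
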