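#' Log likelihood of a Southern-blot fraction time course
#'
#' Each observed fraction is modelled as the model-predicted fraction plus
#' independent Gaussian error with a single shared standard deviation
#' `sigma`. Only the two measured bands — the broken and the repaired
#' fraction — are scored; the modified fraction is their complement and
#' scoring it too would triple-count the compositional constraint.
#' Observed values outside `[0, 1]` (possible under band-level noise) are
#' scored as-is: the Gaussian error model has unbounded support.
#'
#' @param theta Named numeric vector `(alpha, beta, rho, tau, sigma)`,
#'   strictly positive.
#' @param data A `"southern_dataset"` (see [sim_southern()]) or any data
#'   frame with columns `time_h`, `frac_broken`, `frac_repaired`.
#' @param init Initial composition, `c(m=, b=, g=)` in fraction units.
#' @return Scalar log likelihood; `-Inf` if the model cannot be evaluated
#'   at `theta`.
#' @export
log_likelihood <- function(theta, data, init = repair_init()) {
  if (any(!is.finite(theta)) || any(theta <= 0)) return(-Inf)
  sigma <- theta[["sigma"]]
  sol <- tryCatch(
    repair_core(theta[["alpha"]], theta[["beta"]], theta[["rho"]],
                theta[["tau"]], data$time_h,
                init[["m"]], init[["b"]], init[["g"]]),
    error = function(e) {
      warning("model evaluation failed in likelihood: ", conditionMessage(e))
      NULL
    })
  if (is.null(sol)) return(-Inf)
  N <- sol$m + sol$b + sol$g
  fb <- sol$b / N
  fg <- sol$g / N
  if (any(!is.finite(fb)) || any(!is.finite(fg))) return(-Inf)
  sum(stats::dnorm(data$frac_broken, fb, sigma, log = TRUE)) +
    sum(stats::dnorm(data$frac_repaired, fg, sigma, log = TRUE))
}

# Unnormalised log posterior in log-parameter space, with the Jacobian of
# the exp transform so that the chain targets the posterior of theta > 0.
log_posterior_logspace <- function(log_theta, data, priors, init) {
  theta <- exp(log_theta)
  names(theta) <- names(log_theta)
  lp <- log_prior(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  ll <- log_likelihood(theta, data, init)
  if (!is.finite(ll)) return(-Inf)
  lp + ll + sum(log_theta)
}
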