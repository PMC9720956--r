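#' @export
print.dsbr_fit <- function(x, ...) {
  cat("Bayesian fit of the three-state repair kinetics model\n")
  cat(sprintf("  %d observations, %d chains x %d draws (burn-in %d), seed %s\n",
              nrow(x$data), x$n_chains, x$n_draws, x$burn_in, x$seed))
  cat(sprintf("  converged: %s (max split-Rhat %.3f, min ESS %.0f)\n",
              x$converged, max(x$rhat), min(x$ess)))
  cat("Posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.dsbr_fit <- function(object, ...) {
  out <- object$summaries
  class(out) <- c("summary.dsbr_fit", "data.frame")
  attr(out, "converged") <- object$converged
  attr(out, "accept_rate") <- object$accept_rate
  out
}

#' @export
print.summary.dsbr_fit <- function(x, ...) {
  cat("Posterior summary (mean, sd, median, central 95% interval):\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat(sprintf("converged: %s; mean acceptance rate %.2f\n",
              attr(x, "converged"), mean(attr(x, "accept_rate"))))
  invisible(x)
}

#' @export
coef.dsbr_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' Posterior predictive fraction trajectories
#'
#' Evaluates the deterministic model at posterior draws, yielding the bundle
#' of credible fraction curves used to compare the fitted model with
#' global-fraction measurements. With `noise = TRUE`, Gaussian observation
#' noise at each draw's `sigma` is added, giving full posterior predictive
#' replicates of the data.
#'
#' @param object A `"dsbr_fit"`.
#' @param times Time grid in hours (default: the fitted data's times).
#' @param n_curves Number of posterior draws to evaluate.
#' @param noise Add observation noise? Default `FALSE` (pure model curves).
#' @param seed Optional seed for draw selection (and noise).
#' @param ... Unused.
#' @return A list of `"fraction_series"` data frames, one per draw, with the
#'   drawn parameters attached as attribute `"theta"`.
#' @export
predict.dsbr_fit <- function(object, times = NULL, n_curves = 100,
                             noise = FALSE, seed = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), n_curves,
                    replace = n_curves > nrow(object$draws))
  lapply(idx, function(i) {
    th <- object$draws[i, ]
    fr <- predicted_fractions(
      repair_params(th[["alpha"]], th[["beta"]], th[["rho"]], th[["tau"]],
                    sigma = th[["sigma"]]),
      init = object$init, times = times)
    if (noise) {
      fr$frac_m <- fr$frac_m + stats::rnorm(nrow(fr), 0, th[["sigma"]])
      fr$frac_b <- fr$frac_b + stats::rnorm(nrow(fr), 0, th[["sigma"]])
      fr$frac_g <- fr$frac_g + stats::rnorm(nrow(fr), 0, th[["sigma"]])
    }
    attr(fr, "theta") <- th
    fr
  })
}

#' @export
residuals.dsbr_fit <- function(object, ...) {
  th <- apply(object$draws, 2, stats::median)
  fr <- predicted_fractions(
    repair_params(th[["alpha"]], th[["beta"]], th[["rho"]], th[["tau"]],
                  sigma = th[["sigma"]]),
    init = object$init, times = object$data$time_h)
  data.frame(time_h = object$data$time_h,
             broken = object$data$frac_broken - fr$frac_b,
             repaired = object$data$frac_repaired - fr$frac_g)
}

#' Simulate replicate datasets from the posterior predictive
#'
#' @param object A `"dsbr_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of data frames shaped like the fitted data
#'   (`time_h`, `frac_broken`, `frac_repaired`).
#' @export
simulate.dsbr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  curves <- predict(object, n_curves = nsim, noise = TRUE)
  lapply(curves, function(fr) {
    data.frame(time_h = fr$time, frac_broken = fr$frac_b,
               frac_repaired = fr$frac_g)
  })
}

#' Plot a repair-model fit
#'
#' Observed broken (orange) and repaired (green) fractions with a bundle of
#' posterior predictive model curves.
#'
#' @param x A `"dsbr_fit"`.
#' @param n_curves Number of posterior curves to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dsbr_fit <- function(x, n_curves = 50, ...) {
  d <- x$data
  tgrid <- seq(min(d$time_h), max(d$time_h), length.out = 101)
  curves <- predict(x, times = tgrid, n_curves = n_curves)
  graphics::plot(range(tgrid), c(0, 1), type = "n",
                 xlab = "time after induction (h)", ylab = "fraction", ...)
  for (fr in curves) {
    graphics::lines(fr$time, fr$frac_b, col = grDevices::adjustcolor("darkorange", 0.15))
    graphics::lines(fr$time, fr$frac_g, col = grDevices::adjustcolor("forestgreen", 0.15))
  }
  graphics::points(d$time_h, d$frac_broken, pch = 19, col = "darkorange")
  graphics::points(d$time_h, d$frac_repaired, pch = 17, col = "forestgreen")
  graphics::legend("topleft", bty = "n",
                   legend = c("broken (obs)", "repaired (obs)"),
                   pch = c(19, 17), col = c("darkorange", "forestgreen"))
  invisible(x)
}
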