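#' Simulate a Southern-blot-style fraction time course
#'
#' Generates the molecular data modality: observed broken and repaired
#' chromosome fractions on a 0-12 h grid sampled every 2 h. Two noise
#' mechanisms are available. `"fraction"` adds independent Gaussian noise
#' directly to the true model fractions — exactly the error model the
#' likelihood assumes. `"band"` perturbs the three per-lane band
#' intensities (proportional to the m, b, g subpopulations) with Gaussian
#' noise and renormalises by the lane total, mimicking how blot
#' quantification actually works; the resulting fraction errors are
#' correlated and non-Gaussian, making this the standard misspecification
#' stress test for the inference.
#'
#' @param params True [repair_params()]; `params$sigma` is the default
#'   noise scale.
#' @param times Sampling times in hours.
#' @param noise_sd Noise standard deviation; defaults to `params$sigma`.
#' @param noise_mode `"fraction"` or `"band"`.
#' @param g0 Pre-induction repaired fraction (use 0.4 to emulate a leaky
#'   induction strain).
#' @param seed Optional integer seed.
#' @param condition Optional condition label stored with the dataset.
#' @return A data frame of class `"southern_dataset"` with columns
#'   `time_h`, `frac_broken`, `frac_repaired`, carrying the generating
#'   truth as attributes (`truth`, `g0`, `condition`).
#' @examples
#' d <- sim_southern(repair_params(0.23, 0.12, 0.4, tau = 4), seed = 1)
#' d
#' @export
sim_southern <- function(params, times = seq(0, 12, by = 2), noise_sd = NULL,
                         noise_mode = c("fraction", "band"), g0 = 0,
                         seed = NULL, condition = NULL) {
  params <- as_repair_params(params)
  noise_mode <- match.arg(noise_mode)
  if (is.null(noise_sd)) noise_sd <- params$sigma
  stopifnot(noise_sd >= 0, all(times >= 0), all(times <= 24))
  if (!is.null(seed)) set.seed(as.numeric(seed) %% .Machine$integer.max)
  tr <- predicted_fractions(params, repair_init(g0), times)
  n <- length(times)
  if (noise_mode == "fraction") {
    fb <- tr$frac_b + stats::rnorm(n, 0, noise_sd)
    fg <- tr$frac_g + stats::rnorm(n, 0, noise_sd)
  } else {
    im <- tr$frac_m + stats::rnorm(n, 0, noise_sd)
    ib <- tr$frac_b + stats::rnorm(n, 0, noise_sd)
    ig <- tr$frac_g + stats::rnorm(n, 0, noise_sd)
    lane <- im + ib + ig
    fb <- ib / lane
    fg <- ig / lane
  }
  out <- data.frame(time_h = times, frac_broken = fb, frac_repaired = fg)
  attr(out, "truth") <- list(params = params, g0 = g0,
                             noise_mode = noise_mode, noise_sd = noise_sd,
                             seed = seed)
  attr(out, "g0") <- g0
  attr(out, "condition") <- condition
  class(out) <- c("southern_dataset", "data.frame")
  out
}

#' Construct a well ensemble from individual well observations
#'
#' @param wells List of `"well_obs"` objects on a common frame grid.
#' @param condition Optional condition label.
#' @param truth Optional per-well ground-truth data frame.
#' @return An object of class `"well_ensemble"`.
#' @export
well_ensemble <- function(wells, condition = NULL, truth = NULL) {
  stopifnot(length(wells) >= 1)
  grid <- wells[[1]]$time
  for (w in wells) {
    if (!inherits(w, "well_obs") || !isTRUE(all.equal(w$time, grid))) {
      stop("all wells must be 'well_obs' objects on a common frame grid")
    }
  }
  structure(list(wells = wells, time = grid, condition = condition,
                 truth = truth),
            class = "well_ensemble")
}

#' @export
print.well_ensemble <- function(x, ...) {
  cat(sprintf("Microwell ensemble: %d wells, %d frames (%.2g-%.2g h)%s\n",
              length(x$wells), length(x$time), min(x$time), max(x$time),
              if (is.null(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Simulate a microwell time-lapse ensemble
#'
#' Emulates one microfluidic experiment end to end: a chip of `n_chip`
#' wells is loaded with Poisson(`loading_mean`) cells per well, only wells
#' that received exactly one founder cell are retained (the analysable
#' wells), each founder lineage is simulated exactly with [sim_lineage()],
#' and the GFP-delay observation layer is applied per well. Because a chip
#' yields more single-cell wells than a typical usable sample (wells lost
#' to contamination or bubbles in a real experiment), the retained wells
#' are subsampled to `n_wells_target`, drawn uniformly from 80-150 when not
#' given.
#'
#' Two lineage-level knobs reproduce behaviours outside the kinetic model:
#' with probability `p_escape` a founder never breaks (its break rate is
#' forced to zero), producing the observed peak of wells stuck at
#' `r_local = 0`; `p_arrest` passes through to [sim_lineage()] and stops
#' divisions of repaired cells, the error-prone phenotype.
#'
#' @param params True [repair_params()].
#' @param n_chip Number of wells on the chip (default 1032).
#' @param loading_mean Poisson mean occupancy per well.
#' @param frame_interval Frame spacing in hours (default 20 min).
#' @param t_end Horizon in hours.
#' @param p_escape Probability a founder lineage never breaks.
#' @param p_arrest Per-cell division-arrest probability at repair.
#' @param g0 Probability the founder starts already repaired (leaky
#'   induction).
#' @param n_wells_target Number of wells retained; `NULL` draws 80-150.
#' @param gfp_mode GFP observation mode passed to [as_well_observation()].
#' @param seed Optional integer seed (covers loading, escape draws and all
#'   lineage simulations).
#' @param condition Optional condition label.
#' @return A `"well_ensemble"` whose `truth` data frame records, per well,
#'   the escape flag, first break time and first repair time (`NA` when the
#'   event never occurred), plus generation settings as attributes.
#' @examples
#' e <- sim_wells(repair_params(0.23, 0.15, 0.5, tau = 4),
#'                n_wells_target = 40, seed = 1)
#' e
#' @export
sim_wells <- function(params, n_chip = 1032, loading_mean = 1.5,
                      frame_interval = 1 / 3, t_end = 24, p_escape = 0,
                      p_arrest = 0, g0 = 0, n_wells_target = NULL,
                      gfp_mode = c("lineage", "shift"),
                      seed = NULL, condition = NULL) {
  gfp_mode <- match.arg(gfp_mode)
  params <- as_repair_params(params)
  stopifnot(loading_mean > 0, p_escape >= 0, p_escape <= 1,
            g0 >= 0, g0 <= 1)
  if (!is.null(seed)) set.seed(as.numeric(seed) %% .Machine$integer.max)
  occupancy <- stats::rpois(n_chip, loading_mean)
  singles <- which(occupancy == 1L)
  if (length(singles) == 0) {
    stop("no single-cell wells on the chip; adjust loading_mean (Poisson ",
         "occupancy ", loading_mean, " left none with exactly one cell)")
  }
  if (is.null(n_wells_target)) n_wells_target <- sample(80:150, 1)
  if (length(singles) > n_wells_target) {
    singles <- sort(sample(singles, n_wells_target))
  }
  n <- length(singles)
  grid <- seq(0, t_end, by = frame_interval)
  escape <- stats::runif(n) < p_escape
  founder_repaired <- stats::runif(n) < g0
  wells <- vector("list", n)
  t_break <- t_repair <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p_i <- params
    if (escape[i]) p_i$beta <- 0
    init_i <- if (founder_repaired[i]) c(m = 0, b = 0, g = 1) else c(m = 1, b = 0, g = 0)
    l <- sim_lineage(p_i, init = init_i, t_end = t_end, record_times = grid,
                     p_arrest = p_arrest)
    wells[[i]] <- as_well_observation(l, mode = gfp_mode)
    brk <- l$events$time[l$events$type == "break"]
    rep_ <- l$events$time[l$events$type == "repair"]
    if (length(brk)) t_break[i] <- brk[1]
    if (length(rep_)) t_repair[i] <- rep_[1]
  }
  truth <- data.frame(well_id = seq_len(n), chip_well = singles,
                      escape = escape, founder_repaired = founder_repaired,
                      t_break = t_break, t_repair = t_repair)
  out <- well_ensemble(wells, condition = condition, truth = truth)
  attr(out, "settings") <- list(params = params, n_chip = n_chip,
                                loading_mean = loading_mean,
                                p_escape = p_escape, p_arrest = p_arrest,
                                g0 = g0, n_wells_target = n_wells_target,
                                seed = seed)
  attr(out, "n_single_cell") <- sum(occupancy == 1L)
  out
}

#' GFP+ call from a fluorescence intensity
#'
#' A cell is scored GFP+ when its mean green-channel intensity is strictly
#' more than 1.5 times the background level.
#'
#' @param intensity Numeric intensity value(s).
#' @param background Background intensity level (> 0).
#' @return Logical vector.
#' @examples
#' call_gfp(c(149, 150, 151), background = 100)
#' @export
call_gfp <- function(intensity, background) {
  stopifnot(background > 0)
  intensity > 1.5 * background
}

#' Synthetic per-cell fluorescence traces for a well
#'
#' Builds per-frame vectors of cell mean intensities consistent with a well
#' observation: GFP- cells sit at the background level, GFP+ cells at
#' `gfp_brightness` times the background, both plus Gaussian noise.
#' Re-calling cells from these traces with [call_gfp()] recovers the
#' well's GFP counts whenever the noise is small relative to the margin
#' between `1.5 x` background and the two intensity levels.
#'
#' @param well A `"well_obs"` object.
#' @param background Background intensity level (> 0).
#' @param gfp_brightness GFP+ intensity as a multiple of background.
#' @param noise_sd Gaussian intensity noise (same units as `background`).
#' @param seed Optional seed.
#' @return List of class `"intensity_trace"`: `frames` (list of numeric
#'   intensity vectors, one per frame), `background`, `time`.
#' @export
sim_intensity <- function(well, background = 100, gfp_brightness = 3,
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(well, "well_obs"), background > 0, gfp_brightness > 0,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(as.numeric(seed) %% .Machine$integer.max)
  frames <- lapply(seq_along(well$time), function(i) {
    n <- well$n_tot[i]
    k <- well$n_gfp[i]
    base <- c(rep(gfp_brightness * background, k), rep(background, n - k))
    base + stats::rnorm(n, 0, noise_sd)
  })
  structure(list(frames = frames, background = background, time = well$time),
            class = "intensity_trace")
}

#' GFP+ counts recomputed from intensity traces
#'
#' @param trace An `"intensity_trace"` from [sim_intensity()].
#' @return Integer vector of per-frame GFP+ counts.
#' @export
n_gfp_from_intensity <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  vapply(trace$frames, function(x) sum(call_gfp(x, trace$background)),
         integer(1))
}
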