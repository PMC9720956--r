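#' Global GFP+ fraction of a well ensemble
#'
#' Pools all wells frame by frame: `r_global = sum(n_gfp) / sum(n_tot)`.
#' This is the well-size-weighted mean of the local fractions, not their
#' unweighted mean — large colonies dominate it, which is why lineages that
#' never repair (and stay small) barely register in it.
#'
#' @param ensemble A `"well_ensemble"`.
#' @return Data frame with columns `time`, `n_tot`, `n_gfp`, `r_global`.
#' @export
global_fraction <- function(ensemble) {
  stopifnot(inherits(ensemble, "well_ensemble"))
  n_tot <- Reduce(`+`, lapply(ensemble$wells, `[[`, "n_tot"))
  n_gfp <- Reduce(`+`, lapply(ensemble$wells, `[[`, "n_gfp"))
  data.frame(time = ensemble$time, n_tot = n_tot, n_gfp = n_gfp,
             r_global = n_gfp / n_tot)
}

#' Division-to-fluorescence delay distribution
#'
#' Per-well delays `t_gfp - t_lag` between the first division and the first
#' detected GFP+ cell, for wells in which both events occurred; wells
#' missing either event are tallied separately.
#'
#' @param ensemble A `"well_ensemble"`.
#' @return List with `delays` (numeric vector), `n_wells`, `n_never_gfp`,
#'   `n_never_divided`, and summary statistics `mean`, `median`, `iqr`.
#' @export
delay_distribution <- function(ensemble) {
  stopifnot(inherits(ensemble, "well_ensemble"))
  t_lag <- vapply(ensemble$wells, `[[`, numeric(1), "t_lag")
  t_gfp <- vapply(ensemble$wells, `[[`, numeric(1), "t_gfp")
  both <- !is.na(t_lag) & !is.na(t_gfp)
  delays <- t_gfp[both] - t_lag[both]
  list(delays = delays,
       n_wells = length(ensemble$wells),
       n_never_gfp = sum(is.na(t_gfp)),
       n_never_divided = sum(is.na(t_lag)),
       mean = if (length(delays)) mean(delays) else NA_real_,
       median = if (length(delays)) stats::median(delays) else NA_real_,
       iqr = if (length(delays)) stats::IQR(delays) else NA_real_)
}

#' Histogram of final local GFP+ fractions
#'
#' Distribution of `r_local` at the end of the experiment across wells.
#' Bimodality is summarised simply by the mass in the extreme bins: the
#' fraction of wells with `r_local < 0.1` (never/hardly repaired) and
#' `> 0.9` (fully converted).
#'
#' @param ensemble A `"well_ensemble"`.
#' @param t_final Evaluation time, must be on the frame grid (default 24).
#' @param breaks Histogram breaks on `[0, 1]`.
#' @return List with the [graphics::hist()] object (`histogram`), `values`,
#'   `low_mass`, `high_mass`.
#' @export
final_fraction_histogram <- function(ensemble, t_final = 24,
                                     breaks = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(ensemble, "well_ensemble"))
  i <- which(abs(ensemble$time - t_final) < 1e-9)
  if (length(i) != 1) stop("t_final = ", t_final, " is not on the frame grid")
  vals <- vapply(ensemble$wells, function(w) w$r_local[i], numeric(1))
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  list(histogram = h, values = vals,
       low_mass = mean(vals < 0.1), high_mass = mean(vals > 0.9))
}

#' Ranked well-by-frame heat-map matrix
#'
#' The standard single-lineage overview display: one row per well, one
#' column per frame, rows ranked from the smallest to the largest colony at
#' the final frame. Counts are shown as log10, with zero counts mapped to a
#' sentinel value of -1 (below any attainable log10 count, so it renders
#' under the colour floor); colour anchors are the 10th and 90th
#' percentiles of the finite, non-sentinel entries.
#'
#' @param ensemble A `"well_ensemble"`.
#' @param quantity One of `"log_n_tot"`, `"log_n_gfp"`, `"r_local"`.
#' @return An object of class `"well_heatmap"`: list with `matrix`
#'   (wells x frames, in ranked order), `time`, `order` (original well
#'   indices), `t_lag` (per ranked row), `anchors` (10th/90th percentiles),
#'   `quantity`.
#' @export
heatmap_matrix <- function(ensemble,
                           quantity = c("log_n_tot", "log_n_gfp", "r_local")) {
  stopifnot(inherits(ensemble, "well_ensemble"))
  quantity <- match.arg(quantity)
  # rank by final colony size; ties broken lexicographically on the full
  # count trajectories (latest frames first) so the ranking is independent
  # of input well order
  keys <- lapply(rev(seq_along(ensemble$time)), function(j) {
    vapply(ensemble$wells, function(w) w$n_tot[j] + w$n_gfp[j] * 1e-6,
           numeric(1))
  })
  ord <- do.call(order, keys)
  wells <- ensemble$wells[ord]
  get_row <- switch(quantity,
    log_n_tot = function(w) ifelse(w$n_tot > 0, log10(w$n_tot), -1),
    log_n_gfp = function(w) ifelse(w$n_gfp > 0, log10(w$n_gfp), -1),
    r_local = function(w) w$r_local)
  mat <- do.call(rbind, lapply(wells, get_row))
  vals <- mat[is.finite(mat) & mat != -1]
  anchors <- stats::quantile(vals, c(0.1, 0.9), names = FALSE)
  structure(list(matrix = mat, time = ensemble$time, order = ord,
                 t_lag = vapply(wells, `[[`, numeric(1), "t_lag"),
                 anchors = anchors, quantity = quantity),
            class = "well_heatmap")
}

#' @export
plot.well_heatmap <- function(x, ...) {
  graphics::image(x = x$time, y = seq_len(nrow(x$matrix)), z = t(x$matrix),
                  zlim = x$anchors, xlab = "time (h)", ylab = "well (ranked)",
                  main = x$quantity, useRaster = TRUE, ...)
  ok <- !is.na(x$t_lag)
  graphics::points(x$t_lag[ok], seq_len(nrow(x$matrix))[ok], pch = "|",
                   cex = 0.4)
  invisible(x)
}

# Log-linear growth rate of n_tot over frames with time in [t0, t1];
# NA unless >= 4 frames with positive counts are available.
window_rate <- function(well, t0, t1) {
  sel <- well$time >= t0 & well$time <= t1 & well$n_tot > 0
  if (sum(sel) < 4) return(NA_real_)
  stats::coef(stats::lm(log(well$n_tot[sel]) ~ well$time[sel]))[[2]]
}

#' Classify the repair behaviour of a condition
#'
#' Deterministic three-way classification of a well ensemble into the
#' repair regimes distinguishable in single-lineage data:
#' `high_efficacy_error_free` (early repair, most of the population
#' converts), `low_efficacy_error_free` (late/rare repair, low final GFP+
#' fraction, normal growth throughout), and `error_prone_impaired`
#' (repaired cells lose fitness; the local GFP+ fraction can transiently
#' decrease as unrepaired cells outgrow arrested repaired ones — the
#' signature unique to this regime).
#'
#' Three features drive the rule: `F1`, the median division-to-GFP delay
#' among GFP+ wells; `F2`, the final global GFP+ fraction; `F3`, a
#' growth-impairment score — the median over GFP+ wells of the ratio of
#' the log-linear growth rate in the `window` hours after `t_gfp` to the
#' rate in the `window` hours before (wells lacking 4 usable frames on
#' either side, or with a pre-rate too small to normalise by, are
#' excluded); plus the fraction of wells whose `r_local` ever drops by more
#' than `decrease_tol` between consecutive frames. The decision rule: an
#' early repair onset (`F1 <= delay_max`) with high final conversion
#' (`F2 >= r_global_min`) is `high_efficacy_error_free`; early onset whose
#' conversion nevertheless stays low is the fitness-loss signature and
#' gives `error_prone_impaired`, as does overt growth impairment
#' (`F3 < impairment_max`) or a non-monotone-well fraction above
#' `nonmono_max`; everything else (late, rare repair with normal growth)
#' is `low_efficacy_error_free`. The thresholds are heuristics placed in
#' the gaps between the feature distributions of the three synthetic
#' regime presets, exposed here as arguments.
#'
#' @param ensemble A `"well_ensemble"` with at least 20 wells.
#' @param delay_max Maximum median delay (h) counting as early repair.
#' @param r_global_min Minimum final global fraction for high efficacy.
#' @param impairment_max Growth-ratio threshold below which growth is
#'   impaired.
#' @param nonmono_max Maximum tolerated fraction of non-monotone wells.
#' @param window Half-window (h) for the growth-rate fits around `t_gfp`.
#' @param decrease_tol Minimum consecutive-frame drop in `r_local` counted
#'   as a decrease (guards against one-cell counting noise).
#' @return An object of class `"repair_classification"`: list with `label`,
#'   `features` (`median_delay`, `final_r_global`, `growth_ratio`,
#'   `nonmono_fraction`, `n_gfp_wells`), and `low_confidence` (set when
#'   fewer than 5 wells ever show GFP, in which case the label defaults to
#'   low-efficacy).
#' @examples
#' pre <- condition_preset("high_efficacy")
#' e <- sim_wells(pre$params, p_escape = pre$p_escape, seed = 1,
#'                n_wells_target = 60)
#' classify_condition(e)
#' @export
classify_condition <- function(ensemble, delay_max = 8, r_global_min = 0.3,
                               impairment_max = 0.4, nonmono_max = 0.35,
                               window = 2, decrease_tol = 0.05) {
  stopifnot(inherits(ensemble, "well_ensemble"))
  if (length(ensemble$wells) < 20) {
    stop("classification needs at least 20 wells")
  }
  dd <- delay_distribution(ensemble)
  F1 <- dd$median
  gf <- global_fraction(ensemble)
  F2 <- gf$r_global[length(gf$r_global)]
  gfp_wells <- Filter(function(w) !is.na(w$t_gfp), ensemble$wells)
  ratios <- vapply(gfp_wells, function(w) {
    pre <- window_rate(w, w$t_gfp - window, w$t_gfp)
    post <- window_rate(w, w$t_gfp, w$t_gfp + window)
    if (is.na(pre) || is.na(post) || pre < 0.02) return(NA_real_)
    post / pre
  }, numeric(1))
  F3 <- if (any(!is.na(ratios))) stats::median(ratios, na.rm = TRUE) else NA_real_
  nonmono <- mean(vapply(ensemble$wells, function(w) {
    any(diff(w$r_local) < -decrease_tol)
  }, logical(1)))

  low_confidence <- length(gfp_wells) < 5
  early <- !is.na(F1) && F1 <= delay_max
  label <- if (low_confidence) {
    "low_efficacy_error_free"
  } else if (early && F2 >= r_global_min) {
    "high_efficacy_error_free"
  } else if ((early && F2 < r_global_min) ||
             (!is.na(F3) && F3 < impairment_max) || nonmono > nonmono_max) {
    "error_prone_impaired"
  } else {
    "low_efficacy_error_free"
  }
  structure(list(label = label,
                 features = list(median_delay = F1, final_r_global = F2,
                                 growth_ratio = F3,
                                 nonmono_fraction = nonmono,
                                 n_gfp_wells = length(gfp_wells)),
                 low_confidence = low_confidence),
            class = "repair_classification")
}

#' @export
print.repair_classification <- function(x, ...) {
  cat("Repair-behaviour classification:", x$label,
      if (x$low_confidence) "(low confidence: <5 GFP+ wells)" else "", "\n")
  f <- x$features
  cat(sprintf("  median delay %.2f h | final R_global %.3f | growth ratio %s | non-monotone %.2f | GFP+ wells %d\n",
              f$median_delay, f$final_r_global,
              if (is.na(f$growth_ratio)) "NA" else sprintf("%.2f", f$growth_ratio),
              f$nonmono_fraction, f$n_gfp_wells))
  invisible(x)
}
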