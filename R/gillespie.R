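#' Exact stochastic simulation of one founder lineage
#'
#' Simulates the continuous-time Markov jump process underlying the mean
#' model by the direct Gillespie algorithm. Events and propensities:
#' division of a modified cell (`alpha * m`), breakage (`beta * m`), repair
#' (`rho * b`) and division of a repaired cell (`alpha * g`). Broken cells
#' are checkpoint-arrested and never divide. No event can occur before the
#' lag `tau`. Populations in a microwell stay small (hundreds of cells over
#' 24 h), so exact simulation is cheap and tau-leaping is unnecessary.
#'
#' With `p_arrest > 0`, each newly created repaired cell (via a repair event
#' or as the daughter of a repaired division) is, independently with that
#' probability, permanently removed from the dividing pool — the simplest
#' mechanism for the division-arrest phenotype of error-prone conditions.
#' Arrested cells still count in `g`.
#'
#' @param params A [repair_params()] object.
#' @param init Named integer vector `c(m=, b=, g=)`, total >= 1.
#' @param t_end Simulation horizon in hours.
#' @param record_times Frame grid in hours; default 73 frames every 20 min
#'   over 0-24 h, the standard time-lapse schedule.
#' @param p_arrest Per-cell division-arrest probability at repair time.
#' @param seed Optional integer seed; identical seeds give identical event
#'   logs.
#' @param max_pop Population cap; if reached the simulation stops early and
#'   the result is flagged `truncated`.
#' @return An object of class `"lineage"`: list with `record_times`,
#'   `counts` (integer matrix, columns `m`, `b`, `g`, frame sampling by the
#'   last event before each frame), `events` (data frame `time`, `type`
#'   with type in `divide_modified`, `break`, `repair`, `divide_repaired`),
#'   `repaired` (one row per repaired cell ever created: its `birth` time
#'   and the `founder` time of the repair event that founded its clone,
#'   used by the per-cell GFP observation mode), `init`, `params`,
#'   `p_arrest`, `seed`, `truncated`.
#' @examples
#' l <- sim_lineage(repair_params(0.23, 0.12, 0.4, tau = 4), seed = 1)
#' utils::tail(l$counts)
#' @export
sim_lineage <- function(params, init = c(m = 1, b = 0, g = 0), t_end = 24,
                        record_times = seq(0, 24, by = 1 / 3),
                        p_arrest = 0, seed = NULL, max_pop = 1e6) {
  params <- as_repair_params(params)
  stopifnot(t_end > 0, sum(init) >= 1, all(init >= 0),
            all(init == round(init)), p_arrest >= 0, p_arrest <= 1)
  if (!is.null(seed)) set.seed(as.numeric(seed) %% .Machine$integer.max)
  alpha <- params$alpha; beta <- params$beta; rho <- params$rho
  m <- as.integer(init[["m"]]); b <- as.integer(init[["b"]])
  g <- as.integer(init[["g"]])

  # per repaired cell: birth time, founding repair time of its clone,
  # and whether it divides (arrest removes it from the dividing pool)
  rcap <- 64L
  r_birth <- numeric(rcap)
  r_founder <- numeric(rcap)
  nrep <- g
  while (nrep > rcap) rcap <- rcap * 2L
  length(r_birth) <- length(r_founder) <- rcap
  if (g > 0) {
    r_birth[seq_len(g)] <- 0
    r_founder[seq_len(g)] <- -Inf   # pre-induction repaired: GFP+ from t0
  }
  dividing <- if (p_arrest > 0 && g > 0) {
    which(stats::runif(g) >= p_arrest)
  } else {
    seq_len(g)
  }
  add_repaired <- function(birth, founder) {
    nrep <<- nrep + 1L
    if (nrep > rcap) {
      rcap <<- rcap * 2L
      length(r_birth) <<- rcap
      length(r_founder) <<- rcap
    }
    r_birth[nrep] <<- birth
    r_founder[nrep] <<- founder
    if (p_arrest == 0 || stats::runif(1L) >= p_arrest) {
      dividing[length(dividing) + 1L] <<- nrep
    }
  }

  cap <- 4096L
  ev_time <- numeric(cap)
  ev_type <- integer(cap)
  nev <- 0L
  t <- params$tau   # all propensities vanish before the lag
  truncated <- FALSE
  repeat {
    a1 <- alpha * m; a2 <- beta * m; a3 <- rho * b
    a4 <- alpha * length(dividing)
    tot <- a1 + a2 + a3 + a4
    if (tot <= 0) break
    t <- t + stats::rexp(1L, tot)
    if (t > t_end) break
    u <- stats::runif(1L) * tot
    if (u < a1) {
      m <- m + 1L; type <- 1L
    } else if (u < a1 + a2) {
      m <- m - 1L; b <- b + 1L; type <- 2L
    } else if (u < a1 + a2 + a3) {
      b <- b - 1L; g <- g + 1L; type <- 3L
      add_repaired(t, t)
    } else {
      g <- g + 1L; type <- 4L
      # the dividing repaired cells are exchangeable: pick the mother
      # uniformly; the daughter inherits her clone's founding repair time
      mother <- dividing[sample.int(length(dividing), 1L)]
      add_repaired(t, r_founder[mother])
    }
    nev <- nev + 1L
    if (nev > cap) {
      cap <- cap * 2L
      length(ev_time) <- cap
      length(ev_type) <- cap
    }
    ev_time[nev] <- t
    ev_type[nev] <- type
    if (m + b + g >= max_pop) { truncated <- TRUE; break }
  }
  types <- c("divide_modified", "break", "repair", "divide_repaired")
  events <- data.frame(time = ev_time[seq_len(nev)],
                       type = types[ev_type[seq_len(nev)]])
  out <- structure(list(record_times = record_times, counts = NULL,
                        events = events,
                        repaired = data.frame(birth = r_birth[seq_len(nrep)],
                                              founder = r_founder[seq_len(nrep)]),
                        init = init, params = params,
                        p_arrest = p_arrest, seed = seed,
                        truncated = truncated),
                   class = "lineage")
  out$counts <- lineage_counts(out, record_times)
  out
}

#' Lineage state at arbitrary times
#'
#' Replays the event log to give the piecewise-constant counts
#' `(m, b, g)` at the requested times (events at exactly a requested time
#' are included).
#'
#' @param lineage A `"lineage"` object.
#' @param times Numeric vector of times in hours.
#' @return Integer matrix with columns `m`, `b`, `g`.
#' @export
lineage_counts <- function(lineage, times) {
  ev <- lineage$events
  init <- lineage$init
  n_ev <- findInterval(times, ev$time)
  dm <- cumsum(c(0L, (ev$type == "divide_modified") - (ev$type == "break")))
  db <- cumsum(c(0L, (ev$type == "break") - (ev$type == "repair")))
  dg <- cumsum(c(0L, (ev$type == "repair") + (ev$type == "divide_repaired")))
  cbind(m = as.integer(init[["m"]] + dm[n_ev + 1L]),
        b = as.integer(init[["b"]] + db[n_ev + 1L]),
        g = as.integer(init[["g"]] + dg[n_ev + 1L]))
}

#' Convert a simulated lineage to a microwell observation
#'
#' Applies the observation layer of the time-lapse assay: the total cell
#' count per frame and the GFP+ count with the repair-to-fluorescence delay
#' `gamma` applied. Two observation modes are available. The default,
#' `"lineage"`, tracks fluorescence per cell: a repaired cell (and, by
#' inheritance, every descendant in its clone) becomes GFP+ `gamma` hours
#' after the repair event that founded the clone — daughters born of an
#' already-fluorescent mother are fluorescent immediately, so a fully
#' converted well reaches `r_local = 1` as observed. Mode `"shift"` is the
#' cruder population-level count shift `N_GFP(t) = g(max(t - gamma, 0))`;
#' it is adequate for transients but understates late `r_local` by a factor
#' `exp(-alpha * gamma)` because the denominator keeps growing during the
#' delay. Derived per-well summaries: `t_lag`, the first frame time at
#' which the total count exceeds its initial value; `t_gfp`, the first
#' frame time with at least one GFP+ cell (either may be `NA` if the event
#' never happens); and `r_local = n_gfp / n_tot` per frame.
#'
#' @param lineage A `"lineage"` object.
#' @param gamma_delay GFP maturation/detection delay in hours; defaults to
#'   the lineage's own `gamma_delay` parameter.
#' @param mode `"lineage"` (per-cell fluorescence inheritance, default) or
#'   `"shift"` (count shift).
#' @return An object of class `"well_obs"`: list with `time`, `n_tot`,
#'   `n_gfp`, `r_local`, `t_lag`, `t_gfp`, `truncated`.
#' @examples
#' l <- sim_lineage(repair_params(0.23, 0.12, 0.4, tau = 4), seed = 1)
#' w <- as_well_observation(l)
#' c(w$t_lag, w$t_gfp)
#' @export
as_well_observation <- function(lineage, gamma_delay = NULL,
                                mode = c("lineage", "shift")) {
  stopifnot(inherits(lineage, "lineage"))
  mode <- match.arg(mode)
  if (is.null(gamma_delay)) gamma_delay <- lineage$params$gamma_delay
  stopifnot(gamma_delay >= 0)
  tt <- lineage$record_times
  now <- lineage$counts
  n_tot <- now[, "m"] + now[, "b"] + now[, "g"]
  if (mode == "lineage") {
    gfp_on <- pmax(lineage$repaired$birth,
                   lineage$repaired$founder + gamma_delay)
    n_gfp <- findInterval(tt, sort(gfp_on))
  } else {
    n_gfp <- lineage_counts(lineage, pmax(tt - gamma_delay, 0))[, "g"]
  }
  n0 <- sum(lineage$init)
  i_lag <- which(n_tot > n0)[1]
  i_gfp <- which(n_gfp >= 1)[1]
  structure(list(time = tt, n_tot = n_tot, n_gfp = n_gfp,
                 r_local = n_gfp / n_tot,
                 t_lag = if (is.na(i_lag)) NA_real_ else tt[i_lag],
                 t_gfp = if (is.na(i_gfp)) NA_real_ else tt[i_gfp],
                 truncated = lineage$truncated),
            class = "well_obs")
}

#' Frame-wise ensemble mean of simulated lineages
#'
#' Because the underlying jump process is linear, its exact expectation is
#' the ODE mean model; averaging many simulated lineages therefore
#' reproduces [repair_solution()] up to Monte-Carlo error, which this
#' function reports as standard errors.
#'
#' @param lineages List of `"lineage"` objects on a common frame grid
#'   (at least 2).
#' @return Data frame with columns `time`, `m`, `b`, `g`, `se_m`, `se_b`,
#'   `se_g`.
#' @export
ensemble_mean <- function(lineages) {
  stopifnot(length(lineages) >= 2)
  grid <- lineages[[1]]$record_times
  for (l in lineages) {
    if (!isTRUE(all.equal(l$record_times, grid))) {
      stop("lineages are not on a common frame grid")
    }
  }
  n <- length(lineages)
  acc <- function(col) {
    x <- vapply(lineages, function(l) as.numeric(l$counts[, col]),
                numeric(length(grid)))
    list(mean = rowMeans(x),
         se = apply(x, 1, stats::sd) / sqrt(n))
  }
  m <- acc("m"); b <- acc("b"); g <- acc("g")
  data.frame(time = grid, m = m$mean, b = b$mean, g = g$mean,
             se_m = m$se, se_b = b$se, se_g = g$se)
}
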