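# Serialization conventions: CSV for tabular data, JSON for parameters and
# summaries. Times are in hours everywhere; wells CSVs carry both the frame
# index (0-based, frame 0 = t0) and time_h explicitly.

#' Write / read a fraction time course as CSV
#'
#' Columns `time_h`, `frac_broken`, `frac_repaired`. Condition metadata and
#' the pre-induction repaired fraction, when present, go to a JSON sidecar
#' `<path>.json`, which the reader picks up automatically.
#'
#' @param data A `"southern_dataset"` or compatible data frame.
#' @param path Output CSV path.
#' @return `write_fractions_csv`: `path`, invisibly. `read_fractions_csv`:
#'   a `"southern_dataset"` data frame.
#' @export
write_fractions_csv <- function(data, path) {
  req <- c("time_h", "frac_broken", "frac_repaired")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(as.data.frame(data)[req], path, row.names = FALSE)
  meta <- list()
  if (!is.null(attr(data, "condition"))) meta$condition <- attr(data, "condition")
  if (!is.null(attr(data, "g0"))) meta$g0 <- attr(data, "g0")
  if (length(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_fractions_csv
#' @export
read_fractions_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("time_h", "frac_broken", "frac_repaired")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("fractions CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(d, "condition") <- meta$condition
    attr(d, "g0") <- meta$g0
  }
  class(d) <- c("southern_dataset", "data.frame")
  d
}

#' Write / read kinetic parameters as JSON
#'
#' JSON object keyed `alpha`, `beta`, `rho`, `tau`, `gamma_delay`, `sigma`.
#'
#' @param params A [repair_params()] object.
#' @param path JSON file path.
#' @return `write_params_json`: `path`, invisibly; `read_params_json`: a
#'   `"repair_params"` object.
#' @export
write_params_json <- function(params, path) {
  params <- as_repair_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  as_repair_params(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a prior set as JSON
#'
#' JSON object keyed by parameter, each entry `{"mean": ..., "cv": ...}`.
#'
#' @param priors A `"prior_set"`.
#' @param path JSON file path.
#' @return `write_priors_json`: `path`, invisibly; `read_priors_json`: a
#'   `"prior_set"`.
#' @export
write_priors_json <- function(priors, path) {
  jsonlite::write_json(
    lapply(priors, function(p) list(mean = p$mean, cv = p$cv)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_priors_json
#' @export
read_priors_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("alpha", "beta", "rho", "tau", "sigma")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("priors JSON '", path, "' is missing parameter(s): ",
         paste(miss, collapse = ", "))
  }
  structure(lapply(raw[req], function(p) gamma_prior(p$mean, p$cv)),
            class = "prior_set")
}

#' Write / read a well ensemble as CSV
#'
#' Long format, one row per well and frame: columns `well_id`, `frame`
#' (0-based), `time_h`, `n_tot`, `n_gfp`. The reader reconstructs each
#' well's derived quantities (`r_local`, `t_lag`, `t_gfp`), which are pure
#' functions of the stored counts.
#'
#' @param ensemble A `"well_ensemble"`.
#' @param path Output CSV path.
#' @return `write_wells_csv`: `path`, invisibly; `read_wells_csv`: a
#'   `"well_ensemble"`.
#' @export
write_wells_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "well_ensemble"))
  nf <- length(ensemble$time)
  rows <- lapply(seq_along(ensemble$wells), function(i) {
    w <- ensemble$wells[[i]]
    data.frame(well_id = i, frame = seq_len(nf) - 1L, time_h = w$time,
               n_tot = w$n_tot, n_gfp = w$n_gfp)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wells_csv
#' @export
read_wells_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("well_id", "frame", "time_h", "n_tot", "n_gfp")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("wells CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  wells <- lapply(split(d, d$well_id), function(wd) {
    wd <- wd[order(wd$frame), ]
    i_lag <- which(wd$n_tot > wd$n_tot[1])[1]
    i_gfp <- which(wd$n_gfp >= 1)[1]
    structure(list(time = wd$time_h, n_tot = wd$n_tot, n_gfp = wd$n_gfp,
                   r_local = wd$n_gfp / wd$n_tot,
                   t_lag = if (is.na(i_lag)) NA_real_ else wd$time_h[i_lag],
                   t_gfp = if (is.na(i_gfp)) NA_real_ else wd$time_h[i_gfp],
                   truncated = FALSE),
              class = "well_obs")
  })
  well_ensemble(unname(wells))
}

#' Write posterior draws and summary to a directory
#'
#' Writes `draws.csv` (columns `alpha`, `beta`, `rho`, `tau`, `sigma`,
#' `chain`) and `summary.json` (per-parameter mean, sd, median, 95%
#' interval, split-Rhat, ESS, plus sampler settings and seed).
#'
#' @param fit A `"dsbr_fit"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "dsbr_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- as.data.frame(fit$draws)
  draws$chain <- fit$chain
  utils::write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summaries = fit$summaries, converged = fit$converged,
         n_chains = fit$n_chains, n_draws = fit$n_draws,
         burn_in = fit$burn_in, accept_rate = fit$accept_rate,
         seed = fit$seed),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}
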