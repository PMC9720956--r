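# Reference parameter set used across the suite: plausible efficient-repair
# kinetics (3 h doubling, break rate 0.12/h, repair rate 0.40/h, 4 h lag,
# 5% fraction noise).
ref_params <- function() {
  repair_params(alpha = 0.23, beta = 0.12, rho = 0.40, tau = 4,
                gamma_delay = 3, sigma = 0.05)
}

# Independent oracle for the linear mean model: matrix exponential of the
# generator acting on the initial state (clock already lag-shifted).
expm_oracle <- function(params, init, t) {
  A <- matrix(c(params$alpha - params$beta, 0, 0,
                params$beta, -params$rho, 0,
                0, params$rho, params$alpha), 3, 3, byrow = TRUE)
  s <- max(t - params$tau, 0)
  drop(as.matrix(Matrix::expm(Matrix::Matrix(A * s))) %*%
         c(init[["m"]], init[["b"]], init[["g"]]))
}

# Minimal hand-built well observation (for population-statistics tests that
# need exact counts rather than simulated ones).
make_well <- function(time, n_tot, n_gfp) {
  i_lag <- which(n_tot > n_tot[1])[1]
  i_gfp <- which(n_gfp >= 1)[1]
  structure(list(time = time, n_tot = n_tot, n_gfp = n_gfp,
                 r_local = n_gfp / n_tot,
                 t_lag = if (is.na(i_lag)) NA_real_ else time[i_lag],
                 t_gfp = if (is.na(i_gfp)) NA_real_ else time[i_gfp],
                 truncated = FALSE),
            class = "well_obs")
}
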