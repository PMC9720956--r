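test_that("right-hand side implements the three-state balance", {
  p <- repair_params(1, 0, 0)
  expect_equal(repair_rhs(c(m = 1, b = 0, g = 0), p), c(m = 1, b = 0, g = 0))
  p <- repair_params(0.7, 0.3, 0.5)
  expect_equal(repair_rhs(c(m = 0, b = 1, g = 0), p),
               c(m = 0, b = -0.5, g = 0.5))
  p <- repair_params(0.2, 0.1, 0.4)
  expect_equal(repair_rhs(c(m = 2, b = 3, g = 5), p),
               c(m = 0.2, b = -1.0, g = 2.2))
  expect_error(repair_rhs(c(m = -1, b = 0, g = 0), p), "nonnegative")
})

test_that("state is frozen on [0, tau] and pure growth is exponential", {
  p <- ref_params()
  init <- c(m = 0.6, b = 0.3, g = 0.1)
  for (route in list(repair_solution, solve_repair_ode)) {
    tr <- route(p, init, times = c(0, 1, 2.5, 4))
    for (col in c("m", "b", "g")) {
      expect_equal(tr[[col]], rep(init[[col]], 4))
    }
  }
  # beta = rho = 0: modified pool is a pure exponential, b and g stay 0
  p0 <- repair_params(alpha = 0.3, beta = 0, rho = 0, tau = 2)
  tr <- repair_solution(p0, c(m = 2, b = 0, g = 0), times = c(0, 2, 5, 10))
  expect_equal(tr$m, 2 * exp(0.3 * pmax(c(0, 2, 5, 10) - 2, 0)))
  expect_equal(tr$b, rep(0, 4))
  expect_equal(tr$g, rep(0, 4))
  # repaired-only initial condition just grows
  tr <- repair_solution(ref_params(), c(m = 0, b = 0, g = 1),
                        times = c(6, 12))
  expect_equal(tr$g, exp(0.23 * (c(6, 12) - 4)))
  expect_equal(tr$m + tr$b, c(0, 0))
})

test_that("analytic solution matches the matrix-exponential oracle", {
  # frozen oracle values at the reference kinetics, init (1, 0, 0)
  frozen <- rbind(
    c(6, 1.246076730587381, 0.1874700626988611, 0.09557282013221588),
    c(12, 2.410899706417213, 0.5576794123385522, 2.112989931600571),
    c(24, 9.025013499434154, 2.123453655719118, 56.08625300747976))
  sol <- repair_solution(ref_params(), times = frozen[, 1])
  expect_equal(sol$m, frozen[, 2], tolerance = 1e-10)
  expect_equal(sol$b, frozen[, 3], tolerance = 1e-10)
  expect_equal(sol$g, frozen[, 4], tolerance = 1e-10)

  # random sweep incl. nonzero b0/g0 against the oracle computed in-test
  set.seed(42)
  for (i in 1:25) {
    p <- repair_params(alpha = runif(1, 0.01, 1), beta = runif(1, 0.01, 1),
                       rho = runif(1, 0.01, 1), tau = runif(1, 0, 6))
    init <- c(m = runif(1, 0.2, 2), b = runif(1, 0, 1), g = runif(1, 0, 1))
    t <- runif(1, 0, 24)
    ana <- unlist(repair_solution(p, init, times = t)[1, c("m", "b", "g")])
    ora <- expm_oracle(p, init, t)
    expect_lt(max(abs(ana - ora)) / max(abs(ora)), 1e-10)
  }
})

test_that("numerical and analytic routes agree over a random parameter sweep", {
  set.seed(7)
  worst <- 0
  for (i in 1:40) {
    p <- repair_params(alpha = runif(1, 0.01, 1), beta = runif(1, 0.01, 1),
                       rho = runif(1, 0.01, 1), tau = runif(1, 0, 6))
    times <- sort(runif(5, 0, 24))
    ana <- as.matrix(repair_solution(p, times = times)[c("m", "b", "g")])
    num <- as.matrix(solve_repair_ode(p, times = times)[c("m", "b", "g")])
    rel <- max(abs(ana - num)) / max(abs(ana), 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("resonant mode collision (alpha - beta + rho = 0) is handled", {
  # delta = alpha - beta + rho exactly 0: the two exponential modes of b
  # coincide; compare against tight-tolerance quadrature of the ODE
  p <- repair_params(alpha = 0.1, beta = 0.6, rho = 0.5, tau = 1)
  times <- c(2, 6, 12, 24)
  ana <- as.matrix(repair_solution(p, times = times)[c("m", "b", "g")])
  num <- as.matrix(solve_repair_ode(p, times = times,
                                    rtol = 1e-12, atol = 1e-14)[c("m", "b", "g")])
  expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-8)
  # near-resonant values straddling the series-limit threshold
  for (eps in c(1e-6, 1e-9, 1e-12)) {
    p2 <- repair_params(alpha = 0.1, beta = 0.6 + eps, rho = 0.5, tau = 1)
    ana2 <- as.matrix(repair_solution(p2, times = times)[c("m", "b", "g")])
    expect_lt(max(abs(ana2 - ana)) / max(abs(ana)), 1e-4)
  }
})

test_that("predicted fractions are a normalised, monotone composition", {
  p <- ref_params()
  times <- seq(0, 24, by = 0.5)
  fr <- predicted_fractions(p, times = times)
  expect_lt(max(abs(fr$frac_m + fr$frac_b + fr$frac_g - 1)), 1e-12)
  expect_true(all(fr$frac_g >= 0 & fr$frac_g <= 1))
  expect_true(all(diff(fr$frac_g) >= -1e-12))  # repaired fraction never falls
  expect_true(all(fr$frac_b <= 1))
  # no breakage: composition stays (1, 0, 0) forever
  fr0 <- predicted_fractions(repair_params(0.3, 0, 0.4, tau = 2),
                             times = times)
  expect_equal(fr0$frac_m, rep(1, length(times)))
  # the two routes give the same repaired fraction at 24 h
  fr_ode <- predicted_fractions(p, times = 24, method = "ode")
  expect_equal(fr$frac_g[length(times)], fr_ode$frac_g, tolerance = 1e-6)
  expect_error(predicted_fractions(p, init = c(m = 0, b = 0, g = 0),
                                   times = 1), "positive")
})

test_that("solution is linear in the initial condition", {
  p <- ref_params()
  times <- c(5, 10, 20)
  init <- c(m = 0.5, b = 0.2, g = 0.3)
  a <- repair_solution(p, init, times)
  b <- repair_solution(p, 3.7 * init, times)
  expect_equal(3.7 * as.matrix(a[c("m", "b", "g")]),
               as.matrix(b[c("m", "b", "g")]), tolerance = 1e-12)
})

test_that("rmse follows its definition and rejects bad input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3) + 0.25, c(1, 2, 3)), 0.25)
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  expect_error(rmse(1:3, 1:4), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(c(1, NA), c(1, 2)), "finite")
})

test_that("parameter validation rejects negative rates at construction", {
  expect_error(repair_params(-0.1, 0.1, 0.1), "nonnegative")
  expect_error(repair_params(0.1, 0.1, 0.1, tau = -1), "nonnegative")
  expect_error(repair_params(0.1, NA, 0.1), "finite")
})
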