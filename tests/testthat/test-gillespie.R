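test_that("zero rates leave the state absorbing", {
  l <- sim_lineage(repair_params(0, 0, 0, tau = 1),
                   init = c(m = 2, b = 1, g = 3), seed = 1)
  expect_equal(nrow(l$events), 0)
  expect_true(all(l$counts[, "m"] == 2))
  expect_true(all(l$counts[, "b"] == 1))
  expect_true(all(l$counts[, "g"] == 3))
})

test_that("no event occurs before the lag and seeds reproduce event logs", {
  p <- ref_params()
  l1 <- sim_lineage(p, seed = 33)
  l2 <- sim_lineage(p, seed = 33)
  expect_identical(l1$events, l2$events)
  expect_identical(l1$counts, l2$counts)
  expect_identical(l1$repaired, l2$repaired)
  expect_gte(min(l1$events$time), p$tau)
  l3 <- sim_lineage(p, seed = 34)
  expect_false(identical(l1$events, l3$events))
})

test_that("event bookkeeping balances counts", {
  for (s in 1:10) {
    l <- sim_lineage(ref_params(), seed = 400 + s)
    ev <- table(factor(l$events$type,
                       levels = c("divide_modified", "break", "repair",
                                  "divide_repaired")))
    final <- l$counts[nrow(l$counts), ]
    expect_equal(unname(ev["break"]),
                 unname(ev["repair"] + final[["b"]]))
    expect_equal(unname(ev["divide_modified"] + ev["divide_repaired"]),
                 unname(sum(final) - sum(l$init)))
    expect_true(all(l$counts >= 0))
    # one repaired-cell record per repair or repaired division
    expect_equal(nrow(l$repaired),
                 unname(ev["repair"] + ev["divide_repaired"]))
  }
})

test_that("pure-birth mean matches the exponential growth law", {
  p <- repair_params(alpha = 0.3, beta = 0, rho = 0, tau = 1)
  set.seed(52)
  n_rep <- 3000
  finals <- vapply(seq_len(n_rep), function(i) {
    l <- sim_lineage(p, t_end = 10, record_times = c(0, 10))
    sum(l$counts[2, ])
  }, numeric(1))
  # Yule process: mean e^{alpha s}, variance e^{alpha s}(e^{alpha s} - 1)
  s <- 10 - 1
  mu <- exp(0.3 * s)
  se <- sqrt(mu * (mu - 1) / n_rep)
  expect_lt(abs(mean(finals) - mu), 3 * se)
})

test_that("repair waiting times are exponential with rate rho", {
  p <- repair_params(alpha = 0, beta = 0, rho = 0.5, tau = 2)
  set.seed(61)
  waits <- vapply(1:2000, function(i) {
    l <- sim_lineage(p, init = c(m = 0, b = 1, g = 0), t_end = 60,
                     record_times = c(0, 60))
    l$events$time[1] - p$tau
  }, numeric(1))
  # every broken cell ends repaired
  expect_true(all(is.finite(waits)))
  ks <- stats::ks.test(waits, stats::pexp, rate = 0.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble mean tracks the deterministic model", {
  p <- ref_params()
  set.seed(70)
  lins <- lapply(1:2000, function(i) sim_lineage(p))
  em <- ensemble_mean(lins)
  ode <- repair_solution(p, times = em$time)
  ok <- 0
  for (col in c("m", "b", "g")) {
    diff <- abs(em[[col]] - ode[[col]])
    ok <- ok + sum(diff <= 3 * em[[paste0("se_", col)]] + 1e-12)
  }
  expect_gte(ok / (3 * nrow(em)), 0.95)
})

test_that("ensemble mean demands a common grid and handles degenerate input", {
  p <- repair_params(0, 0, 0)
  l1 <- sim_lineage(p, init = c(m = 1, b = 0, g = 0))
  l2 <- sim_lineage(p, init = c(m = 1, b = 0, g = 0))
  em <- ensemble_mean(list(l1, l2))
  expect_true(all(em$m == 1 & em$b == 0 & em$g == 0))
  expect_true(all(em$se_m == 0))
  l3 <- sim_lineage(p, record_times = seq(0, 12, 1))
  expect_error(ensemble_mean(list(l1, l3)), "common frame grid")
})

test_that("population cap truncates with a flag", {
  p <- repair_params(alpha = 2, beta = 0, rho = 0, tau = 0)
  l <- sim_lineage(p, t_end = 24, seed = 3, max_pop = 50)
  expect_true(l$truncated)
  expect_lte(max(rowSums(l$counts)), 50)
})

test_that("GFP observation applies the detection delay per clone", {
  # hand-built lineage: break at 5 h, repair at 6 h, no further events
  l <- structure(list(
    record_times = seq(0, 24, by = 1 / 3),
    events = data.frame(time = c(5, 6), type = c("break", "repair")),
    repaired = data.frame(birth = 6, founder = 6),
    init = c(m = 1, b = 0, g = 0),
    params = ref_params(), p_arrest = 0, seed = NULL, truncated = FALSE),
    class = "lineage")
  l$counts <- lineage_counts(l, l$record_times)
  w <- as_well_observation(l, gamma_delay = 3)
  expect_equal(w$t_gfp, 9)  # first frame at/after repair + gamma
  expect_true(all(w$n_gfp[w$time < 9] == 0))
  expect_true(all(w$n_gfp[w$time >= 9] == 1))
  # in both modes gamma = 0 reduces to the raw repaired count
  for (mode in c("lineage", "shift")) {
    w0 <- as_well_observation(l, gamma_delay = 0, mode = mode)
    expect_equal(w0$n_gfp, unname(l$counts[, "g"]))
  }
  # count-shift mode delays the repaired count wholesale
  ws <- as_well_observation(l, gamma_delay = 3, mode = "shift")
  expect_equal(ws$n_gfp, unname(lineage_counts(l, pmax(l$record_times - 3, 0))[, "g"]))
})

test_that("without breakage there is never a GFP+ cell", {
  l <- sim_lineage(repair_params(0.3, 0, 0.5, tau = 2), seed = 8)
  w <- as_well_observation(l)
  expect_true(all(w$n_gfp == 0))
  expect_true(is.na(w$t_gfp))
  expect_true(all(w$r_local == 0))
  expect_true(all(w$n_gfp <= w$n_tot))
})

test_that("a fully converted well approaches a local fraction of one", {
  # fast break and repair: by 24 h the well should be dominated by GFP+
  p <- repair_params(alpha = 0.3, beta = 0.6, rho = 1.2, tau = 2)
  set.seed(90)
  finals <- vapply(1:40, function(i) {
    w <- as_well_observation(sim_lineage(p))
    w$r_local[length(w$r_local)]
  }, numeric(1))
  expect_gt(median(finals), 0.9)
})
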