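test_that("global fraction is the size-weighted mean of local fractions", {
  tt <- c(0, 12, 24)
  w1 <- make_well(tt, n_tot = c(1, 5, 10), n_gfp = c(0, 5, 10))
  w2 <- make_well(tt, n_tot = c(1, 45, 90), n_gfp = c(0, 0, 0))
  e <- well_ensemble(list(w1, w2))
  gf <- global_fraction(e)
  expect_equal(gf$r_global[3], 0.1)
  mean_local <- mean(c(w1$r_local[3], w2$r_local[3]))
  expect_equal(mean_local, 0.5)
  # identical wells: pooling changes nothing
  ee <- well_ensemble(list(w1, w1, w1))
  expect_equal(global_fraction(ee)$r_global, w1$r_local)
})

test_that("delays subtract first division from first GFP detection", {
  tt <- seq(0, 24, by = 0.2)
  n <- length(tt)
  w <- make_well(tt, n_tot = ifelse(tt >= 2, 2L, 1L),
                 n_gfp = ifelse(tt >= 7.6, 1L, 0L))
  never <- make_well(tt, n_tot = ifelse(tt >= 3, 2L, 1L), n_gfp = rep(0L, n))
  dd <- delay_distribution(well_ensemble(list(w, never)))
  expect_equal(dd$delays, 5.6)
  expect_equal(dd$n_never_gfp, 1)
  expect_equal(dd$n_never_divided, 0)
  expect_equal(dd$median, 5.6)
})

test_that("final-fraction histogram conserves wells and flags extremes", {
  pre <- condition_preset("high_efficacy")
  e <- sim_wells(pre$params, p_escape = 1, n_wells_target = 50, seed = 2)
  fh <- final_fraction_histogram(e, t_final = 24)
  expect_equal(sum(fh$histogram$counts), 50)
  expect_equal(fh$low_mass, 1)
  expect_equal(fh$high_mass, 0)
  expect_error(final_fraction_histogram(e, t_final = 23.9), "frame grid")
})

test_that("heat-map rows are ranked by final colony size", {
  pre <- condition_preset("high_efficacy")
  e <- sim_wells(pre$params, p_escape = 0.3, n_wells_target = 30, seed = 3)
  hm <- heatmap_matrix(e, "log_n_tot")
  expect_equal(dim(hm$matrix), c(30, length(e$time)))
  finals <- hm$matrix[, ncol(hm$matrix)]
  expect_true(all(diff(finals) >= 0))
  expect_length(hm$anchors, 2)
  expect_lte(hm$anchors[1], hm$anchors[2])
  # permuting well order leaves the ranked matrix unchanged
  e_perm <- well_ensemble(e$wells[rev(seq_along(e$wells))])
  hm_perm <- heatmap_matrix(e_perm, "log_n_tot")
  expect_equal(hm$matrix, hm_perm$matrix)
  # zero GFP counts map to the sentinel below the colour floor
  hg <- heatmap_matrix(e, "log_n_gfp")
  zero_frames <- which(e$wells[[hg$order[1]]]$n_gfp == 0)
  expect_true(all(hg$matrix[1, zero_frames] == -1))
  # single-well ensemble degenerates gracefully
  hm1 <- heatmap_matrix(well_ensemble(e$wells[1]), "r_local")
  expect_equal(dim(hm1$matrix), c(1, length(e$time)))
})

test_that("classifier is invariant to well order and duplication", {
  pre <- condition_preset("error_prone")
  e <- sim_wells(pre$params, p_escape = pre$p_escape,
                 p_arrest = pre$p_arrest, n_wells_target = 60, seed = 4)
  c0 <- classify_condition(e)
  c_perm <- classify_condition(well_ensemble(e$wells[sample(60)]))
  expect_identical(c0$label, c_perm$label)
  c_dup <- classify_condition(well_ensemble(c(e$wells, e$wells)))
  expect_identical(c0$label, c_dup$label)
})

test_that("classifier needs enough wells and flags sparse GFP", {
  pre <- condition_preset("high_efficacy")
  e_small <- sim_wells(pre$params, n_wells_target = 10, seed = 5)
  expect_error(classify_condition(e_small), "20 wells")
  # all-escape ensemble: no GFP wells at all -> low-confidence low efficacy
  e_esc <- sim_wells(pre$params, p_escape = 1, n_wells_target = 40, seed = 6)
  cl <- classify_condition(e_esc)
  expect_true(cl$low_confidence)
  expect_equal(cl$label, "low_efficacy_error_free")
})

test_that("classifier recovers the generating regime", {
  for (nm in c("high_efficacy", "low_efficacy", "error_prone")) {
    pre <- condition_preset(nm)
    hits <- vapply(1:5, function(s) {
      e <- sim_wells(pre$params, p_escape = pre$p_escape,
                     p_arrest = pre$p_arrest, g0 = pre$g0, seed = 900 + s)
      classify_condition(e)$label == pre$label
    }, logical(1))
    expect_gte(sum(hits), 4)
  }
})

test_that("mean repaired count is non-decreasing without arrest", {
  p <- ref_params()
  set.seed(31)
  lins <- lapply(1:300, function(i) sim_lineage(p))
  em <- ensemble_mean(lins)
  expect_true(all(diff(em$g) >= 0))  # repairs and divisions only add
})

test_that("pooled GFP fraction approaches the delayed mean-model analogue", {
  # expected GFP+ count under per-cell inheritance: clones founded by
  # repairs before t - gamma, grown for gamma more hours:
  # E[N_GFP(t)] = e^{alpha gamma} g(t - gamma)
  p <- ref_params()
  gap <- function(n, seed) {
    set.seed(seed)
    wells <- lapply(seq_len(n), function(i) as_well_observation(sim_lineage(p)))
    e <- well_ensemble(wells)
    gf <- global_fraction(e)
    sol_now <- repair_solution(p, times = gf$time)
    g_del <- repair_solution(p, times = pmax(gf$time - p$gamma_delay, 0))$g
    pred <- exp(p$alpha * p$gamma_delay) * g_del /
      (sol_now$m + sol_now$b + sol_now$g)
    mean(abs(gf$r_global - pred))
  }
  g_small <- gap(150, 41)
  g_large <- gap(1500, 42)
  expect_lt(g_large, g_small)
  expect_lt(g_large, 0.03)
})
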