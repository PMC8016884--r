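test_that("noise-free synthetic data equals the model curve plus background", {
  d <- generate_dose_response(ascorbate_mech(), "Cu2",
                              conc_grid = c(2.5, 10) * 1e-6, ph = 7,
                              sd_add = 0, background = 2.8, seed = 1,
                              rtol = 1e-6, atol = 1e-14)
  expect_equal(d$dha_uM, attr(d, "model_uM") + 2.8, tolerance = 1e-12)
})

test_that("synthetic datasets are reproducible from their seed", {
  args <- list(mech = ascorbate_mech(), metal = "Cu2",
               conc_grid = c(2.5, 10) * 1e-6, ph = 7, sd_add = 2,
               replicates = 3, rtol = 1e-6, atol = 1e-14)
  d1 <- do.call(generate_dose_response, c(args, seed = 11))
  d2 <- do.call(generate_dose_response, c(args, seed = 11))
  d3 <- do.call(generate_dose_response, c(args, seed = 12))
  expect_identical(d1$dha_uM, d2$dha_uM)
  expect_false(identical(d1$dha_uM, d3$dha_uM))
  # replicates share the mean curve but not the noise
  expect_equal(nrow(d1), 6)
  expect_true(all(d1$dha_uM >= 0))
  m <- attr(d1, "model_uM")
  expect_identical(m, attr(d3, "model_uM"))
})

test_that("ground-truth rate constants are applied before generation", {
  slow <- generate_dose_response(ascorbate_mech(), "Cu2",
                                 conc_grid = 2.5e-6, ph = 7,
                                 true_params = c(R17 = 2.8e4), sd_add = 0,
                                 background = 0, seed = 1,
                                 rtol = 1e-6, atol = 1e-14)
  fast <- generate_dose_response(ascorbate_mech(), "Cu2",
                                 conc_grid = 2.5e-6, ph = 7, sd_add = 0,
                                 background = 0, seed = 1,
                                 rtol = 1e-6, atol = 1e-14)
  expect_lt(slow$dha_uM, fast$dha_uM / 2)
  expect_error(generate_dose_response(ascorbate_mech(), "Cu2",
                                      conc_grid = 300e-6),
               "0-200")
})

test_that("a one-parameter fit recovers the constant behind noise-free data", {
  d <- small_cu_dataset(background = 0)
  pr <- fit_problem(data = d, free = "R17", background = 0,
                    precision = 0.02, rtol = 1e-6, atol = 1e-14)
  fit <- coordinate_search(pr, seed = 3, n_scan = 11)
  expect_lt(abs(fit$best_log10[[1]] - log10(2.8e6)), 0.03)
})

test_that("synthetic OH timecourses start at zero and follow the scenario", {
  sc <- oh_scenario_charrier_like(duration = 3600)
  tc <- generate_oh_timecourse(sc, times = c(0, 900, 1800, 3600),
                               sd_add = 0, seed = 1,
                               rtol = 1e-6, atol = 1e-14)
  expect_equal(tc$oh_uM[1], 0)
  expect_true(all(diff(attr(tc, "model_uM")) >= 0))
  # noise-free series equals the scenario output at its own time grid
  res <- run_oh_scenario(sc, rtol = 1e-6, atol = 1e-14)
  tc2 <- generate_oh_timecourse(sc, times = res$times, sd_add = 0, seed = 1,
                                rtol = 1e-6, atol = 1e-14)
  expect_equal(tc2$oh_uM, res$oh_uM, tolerance = 1e-10)
})

test_that("recovery stays within a tenth of a decade across noisy replicates", {
  # five independently seeded 5%-noise datasets; mean absolute log10
  # recovery error of the copper AH- constant stays below 0.1.  The grid
  # must cover the rising limb of the dose-response: on the oxygen-limited
  # plateau the readout is almost flat in the rate constant upward, so
  # plateau-only designs cannot identify it.
  errs <- vapply(1:5, function(s) {
    d <- generate_dose_response(ascorbate_mech(), "Cu2",
                                conc_grid = c(0.5, 1, 2.5) * 1e-6, ph = 7,
                                sd_add = 0, sd_rel = 0.05, background = 0,
                                seed = 20 + s, rtol = 1e-6, atol = 1e-14)
    pr <- fit_problem(data = d, free = "R17", background = 0,
                      precision = 0.02, rtol = 1e-6, atol = 1e-14)
    fit <- coordinate_search(pr, seed = s, n_scan = 11)
    abs(fit$best_log10[[1]] - log10(2.8e6))
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})
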