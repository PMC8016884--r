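# optimizer unit tests run on analytic objective surfaces (fast); the
# simulation-based objective is exercised on tiny datasets

test_that("the grid search recovers the minimum of a convex surface", {
  truth <- c(4.3, 6.7)
  pr <- fit_problem(free = c("p1", "p2"),
                    objective = function(th) sum((th - truth)^2))
  fit <- grid_search_2d(pr)
  expect_lt(max(abs(fit$best_log10 - truth)), 2 * fit$precision)
  # the returned optimum is never worse than any evaluated point
  expect_true(all(fit$trace$mse >= fit$best_mse - 1e-12))
})

test_that("grid-search ties resolve deterministically", {
  pr <- fit_problem(free = c("p1", "p2"), objective = function(th) 1)
  # a flat surface also trips the boundary diagnostic
  f1 <- suppressWarnings(grid_search_2d(pr, cycles = 2))
  f2 <- suppressWarnings(grid_search_2d(pr, cycles = 2))
  expect_identical(f1$best_log10, f2$best_log10)
  # flat surface: smallest-index grid point wins
  expect_equal(unname(f1$best_log10), c(2, 2))
})

test_that("a best square on the initial boundary raises a warning", {
  pr <- fit_problem(free = c("p1", "p2"),
                    objective = function(th) sum((th - c(2.05, 2.05))^2))
  expect_warning(fit <- grid_search_2d(pr, cycles = 2), "boundary")
  expect_true(fit$boundary_warning)
})

test_that("coordinate search matches a dense scan on a 1-D convex problem", {
  target <- 5.37
  f <- function(th) (th[1] - target)^2
  pr <- fit_problem(free = "p1", objective = f, precision = 0.01)
  fit <- coordinate_search(pr, seed = 7)
  # oracle: dense 1-D scan at the stopping precision
  grid <- seq(2, 9, by = 0.001)
  oracle <- grid[which.min((grid - target)^2)]
  expect_lt(abs(fit$best_log10[[1]] - oracle), 0.01)
  # monotone non-increasing MSE trace
  expect_true(all(diff(fit$trace$mse) <= 1e-12))
  # identical trace under the same seed
  fit2 <- coordinate_search(pr, seed = 7)
  expect_identical(fit$trace, fit2$trace)
  expect_false(identical(
    coordinate_search(pr, seed = 8)$trace$mse[1], fit$trace$mse[1]))
})

test_that("coordinate search handles several parameters", {
  truth <- c(3.1, 5.5, 7.2)
  pr <- fit_problem(free = c("a", "b", "c"), precision = 0.02,
                    objective = function(th) sum((th - truth)^2))
  fit <- coordinate_search(pr, seed = 1)
  expect_lt(max(abs(fit$best_log10 - truth)), 0.05)
})

test_that("the simulation MSE is zero at the generating truth and rises away from it", {
  d <- small_cu_dataset(background = 0)
  pr <- fit_problem(data = d, free = c("R16", "R17"), background = 0,
                    rtol = 1e-6, atol = 1e-14)
  m0 <- fit_mse(pr, c(R16 = 7.7e4, R17 = 2.8e6))
  expect_lt(m0, 1e-4)
  # local identifiability: a tenfold perturbation visibly degrades the fit
  expect_gt(fit_mse(pr, c(R16 = 7.7e4, R17 = 2.8e7)), m0 + 1)
  expect_gt(fit_mse(pr, c(R16 = 7.7e4, R17 = 2.8e5)), m0 + 1)
})

test_that("a null model scores the mean square of the observations", {
  d <- small_cu_dataset(background = 0)
  mech0 <- set_rate_constant(set_rate_constant(ascorbate_mech(), "R16", 0),
                             "R17", 0)
  pr <- fit_problem(data = d, free = c("R16", "R17"), mech = mech0,
                    background = 0, rtol = 1e-6, atol = 1e-14)
  # evaluating at k -> 0 is outside log bounds; call the objective directly
  pred0 <- ascorbox:::.predict_rows(pr, mech0)
  expect_lt(max(abs(pred0)), 1e-3)
  expect_equal(mean((pred0 - d$dha_uM)^2), mean(d$dha_uM^2), tolerance = 1e-4)
})

test_that("fit problems validate their inputs", {
  d <- small_cu_dataset(background = 0)
  expect_error(fit_problem(data = d, free = c("a", "b", "c", "d", "e")),
               "p <= 4")
  pr3 <- fit_problem(data = d, free = c("R14", "R15", "R16"))
  expect_error(grid_search_2d(pr3), "exactly 2")
  expect_error(fit_problem(data = d[, 1:2], free = "R16"), "metal_species|dha_uM")
  expect_error(set_rate_constant(ascorbate_mech(), "R999", 1), "no reaction")
})

test_that("dataset CSV round-trips through the documented schema", {
  d <- small_cu_dataset(background = 0)
  path <- tempfile(fileext = ".csv")
  write_dha_csv(d, path)
  back <- read_dha_csv(path)
  expect_equal(back$conc_M, d$conc_M)
  expect_equal(back$dha_uM, d$dha_uM, tolerance = 1e-12)
  expect_error(read_dha_csv({
    p2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(x = 1), p2, row.names = FALSE)
    p2
  }), "missing columns")
  unlink(path)
})

test_that("rate-law comparison ranks the generating law first on its own data", {
  d <- small_cu_dataset(background = 0)   # generated by catalytic-111
  # some scan points in the far corners of the box are unintegrable and
  # get penalized; the optimizers summarize that in one warning
  ranking <- suppressWarnings(compare_rate_laws(
    d,
    variants = list("catalytic-111" = "R17", "cu-halfO2" = "R17",
                    "cu-chloride-law" = "R16", "redox" = "R17"),
    algo = "coord", seed = 1, n_scan = 7, background = 0, precision = 0.1,
    rtol = 1e-6, atol = 1e-14))
  expect_equal(ranking$variant[1], "catalytic-111")
  # the half-order chloride-media law cannot reproduce the oxygen-limited
  # plateau: it ranks at or near the bottom
  expect_gte(match("cu-chloride-law", ranking$variant), 3)
})
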