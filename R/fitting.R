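# Rate-constant estimation against DHA dose-response data: mean-squared-
# error objective, recursive 11x11 two-dimensional grid search, cyclic
# coordinate search for more than two free constants, and rate-law
# comparison.

#' Define a rate-constant fitting problem
#'
#' @param data Dataset of DHA observations: data.frame with columns
#'   `metal_species` (`"Fe2"`, `"Fe3"`, `"Cu2"`), `conc_M` (coil-1 basis),
#'   `dha_uM`, `ph`.  Rows are grouped into datasets by (metal, pH); the
#'   objective is the sum over datasets of the per-dataset mean squared
#'   error (uM^2).
#' @param free Base reaction ids whose rate constants are fitted (1-4),
#'   e.g. `c("R16", "R17")`.
#' @param variant Mechanism variant passed to [build_ascorbate_mechanism()],
#'   or an `aa_mechanism` via `mech`.
#' @param mech Optional pre-built mechanism (overrides `variant`).
#' @param bounds 2 x p matrix (rows lower/upper) of log10 bounds per free
#'   constant, or a single c(lo, hi) recycled; default log10 k in \[2, 9\].
#' @param precision Stopping width in log10 units for the coordinate
#'   search (and the reporting precision of the grid search).
#' @param background Background DHA (uM) added to model predictions before
#'   comparison with observations (the synthetic generator adds the same).
#' @param objective Optional function(log10-parameter vector) -> MSE that
#'   replaces the simulation-based objective (used to exercise the
#'   optimizers on analytic surfaces).
#' @param rtol,atol Integration tolerances used inside the objective
#'   (slightly looser than the reporting defaults: the induced readout
#'   error is far below measurement noise).
#' @param maxsteps Internal integrator step cap per objective evaluation;
#'   evaluations that exceed it are penalized rather than retried.
#' @param protocol_args Extra arguments for [run_protocol()].
#' @return An `aa_fit_problem`.
#' @export
fit_problem <- function(data = NULL, free = c("R16", "R17"),
                        variant = "catalytic-111", mech = NULL,
                        bounds = c(2, 9), precision = 0.01,
                        background = 2.8, objective = NULL,
                        rtol = 1e-6, atol = 1e-14, maxsteps = 50000,
                        protocol_args = list()) {
  p <- length(free)
  if (is.null(objective)) {
    stopifnot(p >= 1, p <= 4)
    stopifnot(is.data.frame(data),
              all(c("metal_species", "conc_M", "dha_uM", "ph") %in% names(data)))
  }
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == 2, ncol(bounds) == p)
  } else {
    bounds <- matrix(rep(bounds, p), 2, p)
  }
  colnames(bounds) <- free
  stopifnot(all(is.finite(bounds)), all(bounds[1, ] < bounds[2, ]))
  if (is.null(mech) && is.null(objective)) mech <- build_ascorbate_mechanism(variant)
  structure(list(data = data, free = free, mech = mech, bounds = bounds,
                 precision = precision, background = background,
                 objective = objective, rtol = rtol, atol = atol,
                 maxsteps = maxsteps, protocol_args = protocol_args,
                 state = new.env(parent = emptyenv())),
            class = "aa_fit_problem")
}

# model-predicted readout (uM, incl. background) for every dataset row
.predict_rows <- function(problem, mech) {
  d <- problem$data
  out <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    args <- c(list(mech = mech, metal = d$metal_species[i],
                   conc = d$conc_M[i], ph = d$ph[i],
                   background = problem$background * 1e-6,
                   rtol = problem$rtol, atol = problem$atol, n_out = 2,
                   maxsteps = problem$maxsteps),
              problem$protocol_args)
    out[i] <- tryCatch(
      suppressWarnings(do.call(run_protocol, args)$readout_uM),
      error = function(e) NA_real_)
  }
  out
}

# objective on the log10 scale; integration failures are penalized and
# counted (the optimizers report the count once)
.mse_log10 <- function(problem, theta) {
  if (!is.null(problem$objective)) return(problem$objective(theta))
  mech <- problem$mech
  for (j in seq_along(problem$free))
    mech <- set_rate_constant(mech, problem$free[j], 10^theta[j])
  pred <- .predict_rows(problem, mech)
  if (anyNA(pred)) {
    problem$state$n_failed <- (problem$state$n_failed %||% 0L) + 1L
    return(1e12)
  }
  d <- problem$data
  grp <- interaction(d$metal_species, d$ph, drop = TRUE)
  sum(tapply((pred - d$dha_uM)^2, grp, mean))
}

.report_failures <- function(problem) {
  n <- problem$state$n_failed %||% 0L
  if (n > 0L)
    warning(n, " objective evaluation(s) hit an integration failure and ",
            "were penalized", call. = FALSE)
  problem$state$n_failed <- 0L
  invisible(n)
}

#' Mean squared error of a parameter combination
#'
#' Runs the protocol model at every dataset point and returns the sum over
#' (metal, pH) datasets of the mean squared DHA error, in uM^2.
#'
#' @param problem An `aa_fit_problem`.
#' @param k Named rate constants (natural scale) for the free reactions.
#' @return MSE (uM^2).
#' @export
fit_mse <- function(problem, k) {
  stopifnot(all(problem$free %in% names(k)))
  .mse_log10(problem, log10(unname(k[problem$free])))
}

.new_fit_result <- function(problem, best_theta, best_mse, trace, seed = NULL,
                            boundary = FALSE) {
  structure(list(best_k = setNames(10^best_theta, problem$free),
                 best_log10 = setNames(best_theta, problem$free),
                 best_mse = best_mse, trace = trace, seed = seed,
                 boundary_warning = boundary),
            class = "aa_fit_result")
}

#' @export
print.aa_fit_result <- function(x, ...) {
  cat("<aa_fit_result>\n  best constants:",
      paste(sprintf("%s = %.4g", names(x$best_k), x$best_k), collapse = ", "),
      sprintf("\n  best MSE: %.6g (%d evaluations)\n",
              x$best_mse, nrow(x$trace)))
  invisible(x)
}

#' Recursive two-dimensional grid search
#'
#' The two free rate constants are varied on an 11 x 11 log-spaced grid;
#' each of the 10 x 10 unit squares is scored by the mean of its four
#' corner MSEs (used to flag searches pressed against the bounds), and the
#' refinement region for the next cycle is the box centered on the best
#' evaluated grid point with a half-width of one grid spacing, so the
#' running optimum always stays interior while the box shrinks fivefold
#' per axis per cycle.  After `cycles` refinements the evaluated grid
#' point with the minimum MSE is the best fit.  Ties resolve toward the
#' smallest grid indices, so the search is deterministic.
#'
#' @param problem An `aa_fit_problem` with exactly two free parameters.
#' @param cycles Number of refinement cycles.
#' @param grid_n Grid points per axis.
#' @return An `aa_fit_result` with the final grid spacing in `precision`;
#'   `boundary_warning` is set (with a warning) if the best unit square
#'   touches the initial search box on the first cycle.
#' @export
grid_search_2d <- function(problem, cycles = 4, grid_n = 11) {
  stopifnot(inherits(problem, "aa_fit_problem"))
  p <- ncol(problem$bounds)
  if (p != 2) stop("the 2-D grid search needs exactly 2 free parameters")
  lo <- problem$bounds[1, ]; hi <- problem$bounds[2, ]
  lo0 <- lo; hi0 <- hi
  trace <- list()
  best <- list(theta = NULL, mse = Inf)
  boundary <- FALSE
  spacing <- (hi - lo) / (grid_n - 1)
  for (cy in seq_len(cycles)) {
    g1 <- seq(lo[1], hi[1], length.out = grid_n)
    g2 <- seq(lo[2], hi[2], length.out = grid_n)
    mse <- matrix(NA_real_, grid_n, grid_n)
    for (j in seq_len(grid_n)) {
      for (i in seq_len(grid_n)) {
        mse[i, j] <- .mse_log10(problem, c(g1[i], g2[j]))
      }
    }
    trace[[cy]] <- data.frame(cycle = cy,
                              par1 = rep(g1, times = grid_n),
                              par2 = rep(g2, each = grid_n),
                              mse = as.vector(mse))
    # best grid point; column-major scan so ties resolve to smallest (i, j)
    w <- which(mse == min(mse), arr.ind = TRUE)
    w <- w[order(w[, 2], w[, 1]), , drop = FALSE][1, ]
    if (mse[w[1], w[2]] < best$mse) {
      best <- list(theta = c(g1[w[1]], g2[w[2]]), mse = mse[w[1], w[2]])
    }
    if (cy == 1L) {
      # 4-corner square scores, for the bounds diagnostic
      sq <- mse[-grid_n, -grid_n] + mse[-1, -grid_n] +
        mse[-grid_n, -1] + mse[-1, -1]
      ws <- which(sq == min(sq), arr.ind = TRUE)
      ws <- ws[order(ws[, 2], ws[, 1]), , drop = FALSE][1, ]
      if (ws[1] == 1L || ws[1] == grid_n - 1L ||
          ws[2] == 1L || ws[2] == grid_n - 1L) {
        boundary <- TRUE
        warning("best unit square lies on the boundary of the initial ",
                "search box; consider widening the bounds")
      }
    }
    spacing <- (hi - lo) / (grid_n - 1)
    lo <- pmax(lo0, best$theta - spacing)
    hi <- pmin(hi0, best$theta + spacing)
  }
  res <- .new_fit_result(problem, best$theta, best$mse,
                         do.call(rbind, trace), boundary = boundary)
  res$precision <- max((hi - lo) / (grid_n - 1))
  res$n_failed <- .report_failures(problem)
  res
}

#' Cyclic coordinate search
#'
#' Starting from random (seeded) initial log10 rate constants, one
#' constant at a time is scanned over the current search range while the
#' others stay fixed, keeping the scan minimum.  When a full cycle brings
#' no improvement the range is halved; the optimization stops once the
#' range falls below the problem's `precision` (log10 units).  The MSE
#' trace is monotone non-increasing and reproducible for a given seed.
#'
#' @param problem An `aa_fit_problem`.
#' @param seed Integer seed for the random initial point.
#' @param n_scan Points per axis scan.
#' @param shrink Range shrink factor on a no-improvement cycle.
#' @param max_cycles Safety cap on cycles.
#' @return An `aa_fit_result` (with `seed` recorded).
#' @export
coordinate_search <- function(problem, seed = 1, n_scan = 21, shrink = 0.5,
                              max_cycles = 200) {
  stopifnot(inherits(problem, "aa_fit_problem"))
  lo <- problem$bounds[1, ]; hi <- problem$bounds[2, ]
  p <- length(lo)
  set.seed(seed)
  theta <- lo + runif(p) * (hi - lo)
  width <- (hi - lo) / 2
  cur <- .mse_log10(problem, theta)
  trace <- list(data.frame(cycle = 0, t(setNames(theta, problem$free)),
                           mse = cur, width = max(width)))
  cycle <- 0
  while (max(width) > problem$precision && cycle < max_cycles) {
    cycle <- cycle + 1
    improved <- FALSE
    for (j in seq_len(p)) {
      grid <- seq(max(lo[j], theta[j] - width[j]),
                  min(hi[j], theta[j] + width[j]), length.out = n_scan)
      vals <- vapply(grid, function(g) {
        th <- theta; th[j] <- g
        .mse_log10(problem, th)
      }, numeric(1))
      b <- which.min(vals)
      if (vals[b] < cur) {
        if (abs(grid[b] - theta[j]) > 0) improved <- TRUE
        cur <- vals[b]
        theta[j] <- grid[b]
      }
    }
    if (!improved) width <- width * shrink
    trace[[length(trace) + 1L]] <-
      data.frame(cycle = cycle, t(setNames(theta, problem$free)), mse = cur,
                 width = max(width))
  }
  res <- .new_fit_result(problem, theta, cur, do.call(rbind, trace),
                         seed = seed)
  res$n_failed <- .report_failures(problem)
  res
}

#' Compare mechanism variants / rate laws on the same data
#'
#' Fits each candidate rate-law variant to the dataset and ranks the
#' variants by their best achievable MSE.
#'
#' @param data Dataset (see [fit_problem()]).
#' @param variants Named list: variant name -> character vector of free
#'   base reaction ids for that variant.
#' @param algo `"grid"` (2 free parameters) or `"coord"`.
#' @param seed Seed for coordinate searches.
#' @param n_scan,shrink Coordinate-search controls (see
#'   [coordinate_search()]).
#' @param ... Passed to [fit_problem()].
#' @return data.frame ranked by MSE with the fitted constants attached as
#'   the `fits` attribute.
#' @export
compare_rate_laws <- function(data,
                              variants = list(
                                "catalytic-111" = c("R16", "R17"),
                                "cu-halfO2" = c("R16", "R17"),
                                "cu-chloride-law" = c("R16"),
                                "redox" = c("R16", "R17")),
                              algo = c("grid", "coord"), seed = 1,
                              n_scan = 21, shrink = 0.5, ...) {
  algo <- match.arg(algo)
  fits <- list()
  rows <- list()
  for (v in names(variants)) {
    free <- variants[[v]]
    pr <- fit_problem(data = data, free = free, variant = v, ...)
    fit <- if (algo == "grid" && length(free) == 2) {
      grid_search_2d(pr)
    } else {
      coordinate_search(pr, seed = seed, n_scan = n_scan, shrink = shrink)
    }
    fits[[v]] <- fit
    rows[[v]] <- data.frame(variant = v, mse = fit$best_mse,
                            constants = paste(sprintf("%s=%.3g",
                                                      names(fit$best_k),
                                                      fit$best_k),
                                              collapse = ", "),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mse), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Read / write the dose-response dataset CSV
#'
#' Columns: `metal_species`, `conc_M` (coil-1 basis), `dha_uM`, `ph`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_dha_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("metal_species", "conc_M", "dha_uM", "ph")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dataset is missing columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' @rdname read_dha_csv
#' @param data Dataset to write.
#' @export
write_dha_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}
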