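# Synthetic datasets emulating real measured DHA dose-response
# curves and OH. timecourses, generated from known ground-truth rate
# constants.  These stand in for the raw measurements (which exist only as
# figure points) in all parameter-recovery testing.

#' Generate a noisy synthetic DHA dose-response dataset
#'
#' Runs the two-coil protocol at every grid concentration with the given
#' ground-truth rate constants, then adds the background DHA offset and
#' measurement noise: `readout = model + background + N(0, sd_add + sd_rel
#' * model)`, truncated at zero.  Replicates share the same mean curve.
#' The result is reproducible from (true parameters, grid, noise model,
#' seed).
#'
#' @param mech Mechanism or variant name (passed to
#'   [build_ascorbate_mechanism()] when a string).
#' @param metal,ph As in [run_protocol()].
#' @param conc_grid Metal concentrations, coil-1 basis (mol/L), within the
#'   0-200 uM range the assay covers.
#' @param true_params Named ground-truth constants applied via
#'   [set_rate_constant()] (NULL keeps the mechanism's values).
#' @param sd_add Additive noise standard deviation (uM).
#' @param sd_rel Multiplicative noise, as a fraction of the model readout.
#' @param background Background DHA offset (uM); 2.8 uM is the observed
#'   blank level.
#' @param replicates Replicate measurements per concentration.
#' @param seed Integer seed; required for reproducibility.
#' @param ... Passed to [run_protocol()].
#' @return data.frame with columns `metal_species`, `conc_M`, `dha_uM`,
#'   `ph`, `replicate`; the noise-free curve and the truth are attached as
#'   attributes `model_uM` and `true_params`.
#' @export
generate_dose_response <- function(mech = "catalytic-111", metal = "Cu2",
                                   conc_grid = c(2.5, 5, 10, 25, 50, 100) * 1e-6,
                                   ph = 7, true_params = NULL, sd_add = 1,
                                   sd_rel = 0, background = 2.8,
                                   replicates = 1, seed = 1, ...) {
  if (is.character(mech)) mech <- build_ascorbate_mechanism(mech)
  if (any(conc_grid < 0) || any(conc_grid > 200e-6))
    stop("concentration grid must lie within 0-200 uM (coil-1 basis)")
  for (id in names(true_params)) mech <- set_rate_constant(mech, id,
                                                           true_params[[id]])
  model <- vapply(conc_grid, function(cc)
    run_protocol(mech, metal = metal, conc = cc, ph = ph, ...)$readout_uM,
    numeric(1))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in seq_len(replicates)) {
    noise <- if (sd_add > 0 || sd_rel > 0)
      rnorm(length(model), 0, sd_add + sd_rel * model) else 0
    rows[[r]] <- data.frame(metal_species = metal, conc_M = conc_grid,
                            dha_uM = pmax(model + background + noise, 0),
                            ph = ph, replicate = r, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "model_uM") <- model
  attr(out, "true_params") <- true_params
  out
}

#' Generate a noisy synthetic OH. timecourse
#'
#' Samples the cumulative OH. production of [run_oh_scenario()] at the
#' requested times and adds truncated Gaussian noise.
#'
#' @param scenario An [oh_scenario()].
#' @param times Sampling times (s) within the scenario duration.
#' @param true_params Named rate-constant overrides.
#' @param sd_add Additive noise (uM).
#' @param seed Integer seed.
#' @param ... Passed to [run_oh_scenario()].
#' @return data.frame with columns `time_s`, `oh_uM`; the noise-free
#'   series is attached as attribute `model_uM`.
#' @export
generate_oh_timecourse <- function(scenario, times = NULL, true_params = NULL,
                                   sd_add = 0.1, seed = 1, ...) {
  mech <- build_ascorbate_mechanism("catalytic-111")
  for (id in names(true_params)) mech <- set_rate_constant(mech, id,
                                                           true_params[[id]])
  res <- run_oh_scenario(scenario, mech = mech, ...)
  if (is.null(times)) times <- res$times
  model <- approx(res$times, res$oh_uM, xout = times, rule = 2)$y
  model[times == 0] <- 0
  if (!is.null(seed)) set.seed(seed)
  noise <- if (sd_add > 0) rnorm(length(model), 0, sd_add) else 0
  out <- data.frame(time_s = times, oh_uM = pmax(model + noise, 0))
  attr(out, "model_uM") <- model
  out
}
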