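# Simulation of the online two-coil DHA instrument: flow mixing of the
# ascorbic acid and metal streams, incubation in reaction coil-1 (20 min,
# 37 C), addition of the oPDA derivatization stream, and coil-2 (10 min,
# room temperature, acidic), with the DHA-oPDA adduct as the readout.

#' A reagent stream
#' @param flow Flow rate, mL/min (> 0).
#' @param composition Named concentrations (mol/L) carried by the stream.
#' @return An `aa_stream`.
#' @export
stream <- function(flow, composition = c()) {
  stopifnot(flow > 0, all(composition >= 0))
  structure(list(flow = flow, composition = composition), class = "aa_stream")
}

#' Mix streams at a flow junction
#'
#' Concentrations after mixing are the flow-weighted means of the stream
#' concentrations, which conserves the molar flux of every species across
#' the junction.
#'
#' @param streams List of [stream()] objects.
#' @return List with `flow` (total, mL/min) and `composition` (mol/L).
#' @export
mix_streams <- function(streams) {
  stopifnot(length(streams) >= 1)
  total <- sum(vapply(streams, `[[`, numeric(1), "flow"))
  sp <- unique(unlist(lapply(streams, function(s) names(s$composition))))
  comp <- setNames(numeric(length(sp)), sp)
  for (s in streams) {
    for (nm in names(s$composition))
      comp[nm] <- comp[nm] + s$flow / total * s$composition[[nm]]
  }
  list(flow = total, composition = comp)
}

# initial metal salt composition on the coil-1 concentration basis
.metal_composition <- function(metal, conc, fe2_preox = 0.1) {
  switch(metal,
    none = c(),
    Fe2 = c("Fe2+" = conc * (1 - fe2_preox), "Fe3+" = conc * fe2_preox,
            "SO42-" = conc),
    Fe3 = c("Fe3+" = conc, "SO42-" = 1.5 * conc),
    Cu2 = c("Cu2+" = conc, "SO42-" = conc),
    stop("unsupported metal form '", metal,
         "' (use none, Fe2 [FeSO4], Fe3 [Fe2(SO4)3] or Cu2 [CuSO4])")
  )
}

#' Coil-1 segment conditions for one experiment
#'
#' Builds the initial composition and conditions of the first reaction
#' coil: 100 uM total ascorbic acid after the 1:1 mixing of the 200 uM
#' working solution with the metal stream, the metal salt at its coil-1
#' concentration (Fe(II) stocks partially pre-oxidized), chloride carried
#' by the HCl pH adjustment for pH 2.8 runs, 37 C, 20 min, clamped pH,
#' air-saturated oxygen at the coil temperature.
#'
#' @param metal `"none"`, `"Fe2"` (FeSO4), `"Fe3"` (Fe2(SO4)3) or `"Cu2"`
#'   (CuSO4).
#' @param conc Metal concentration in coil-1 (mol/L).
#' @param ph 2.8 or 7.0 (any value accepted; these two match the assay).
#' @param aa Total ascorbic acid in coil-1 (mol/L).
#' @param fe2_preox Fraction of an Fe(II) stock already oxidized to
#'   Fe(III) when the experiment starts (stock aging).
#' @param temperature,duration Coil-1 incubation conditions.
#' @return An `aa_conditions`.
#' @export
coil1_conditions <- function(metal = "none", conc = 0, ph = 2.8, aa = 1e-4,
                             fe2_preox = 0.1, temperature = 37,
                             duration = 1200) {
  init <- c(AH2 = aa, .metal_composition(metal, conc, fe2_preox))
  if (ph <= 4) init["Cl-"] <- 1.6e-3  # HCl pH adjustment
  segment_conditions(ph = ph, temperature = temperature, duration = duration,
                     initial = init)
}

#' Run the full two-coil protocol
#'
#' Chains the coil-1 incubation into the coil-2 derivatization exactly as
#' the instrument plumbs them: the coil-1 effluent (2.2 mL/min) meets the
#' oPDA stream (1.1 mL/min of 46 mM oPDA in 0.1 M HCl for pH 2.8 runs,
#' 20 mM for pH 7 runs), diluting the reaction mixture by 2/3, and reacts
#' for 10 min at room temperature at acidic pH.  The readout is the
#' DHA-oPDA adduct (plus any underivatized DHA) at the coil-2 exit.
#'
#' With `readout_basis = "coil1"` (default) the coil-2 concentration is
#' divided by the 2/3 dilution so the value is expressed on the coil-1
#' concentration scale, on which the theoretical maximum equals the 100 uM
#' coil-1 ascorbic acid; `"coil2"` reports the concentration actually in
#' coil 2.
#'
#' @inheritParams coil1_conditions
#' @param mech An `aa_mechanism`.
#' @param readout_basis `"coil1"` or `"coil2"`.
#' @param coil2 Simulate the second coil?  (`FALSE` stops after coil-1.)
#' @param coil2_duration,coil2_temperature,coil2_ph Derivatization coil
#'   conditions; `coil2_ph` defaults to 2.8 for acidic runs and 2.0 for
#'   pH 7 runs (the 0.1 M HCl carried by the oPDA stream overwhelms the
#'   HEPES buffer).
#' @param background Additive background DHA (mol/L-equivalent on the
#'   readout basis) added to the returned readout; zero for the bare model.
#' @param ledger Carry the flux ledger through both segments.
#' @param rtol,atol,n_out,maxsteps Integration controls passed to
#'   [integrate_segment()].
#' @return List with `readout_uM`, `coil1` and `coil2` segment results and
#'   the readout basis.
#' @export
run_protocol <- function(mech, metal = "none", conc = 0, ph = 2.8,
                         aa = 1e-4, fe2_preox = 0.1,
                         readout_basis = c("coil1", "coil2"),
                         coil2 = TRUE, coil2_duration = 600,
                         coil2_temperature = 25, coil2_ph = NULL,
                         background = 0, ledger = FALSE,
                         rtol = 1e-8, atol = 1e-16, n_out = 10,
                         maxsteps = 200000) {
  readout_basis <- match.arg(readout_basis)
  c1 <- coil1_conditions(metal, conc, ph = ph, aa = aa,
                         fe2_preox = fe2_preox)
  r1 <- integrate_segment(mech, c1, ledger = ledger, n_out = n_out,
                          rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (!coil2) {
    dha <- final_state(r1)[["DHA"]]
    return(list(readout_uM = dha * 1e6 + background * 1e6, coil1 = r1,
                coil2 = NULL, basis = "coil1"))
  }
  if (is.null(coil2_ph)) coil2_ph <- if (ph <= 4) 2.8 else 2.0
  opda <- if (ph <= 4) 46e-3 else 20e-3
  eff <- pmax(final_state(r1), 0)   # clip integrator-scale negatives
  eff <- eff[setdiff(names(eff), c("H+", "OH-", "H2O"))]
  mixed <- mix_streams(list(
    stream(2.2, eff),
    stream(1.1, c(oPDA = opda, "Cl-" = 0.1,
                  O2 = o2_saturation(coil2_temperature)))
  ))
  init2 <- mixed$composition
  init2 <- init2[init2 > 0]
  c2 <- segment_conditions(ph = coil2_ph, temperature = coil2_temperature,
                           duration = coil2_duration, initial = init2,
                           o2 = unname(init2["O2"]))
  r2 <- integrate_segment(mech, c2, ledger = ledger, n_out = n_out,
                          rtol = rtol, atol = atol, maxsteps = maxsteps)
  fin <- final_state(r2)
  dha <- fin[["DHAoPDA"]] + fin[["DHA"]]
  if (readout_basis == "coil1") dha <- dha / (2 / 3)
  list(readout_uM = dha * 1e6 + background * 1e6, coil1 = r1, coil2 = r2,
       basis = readout_basis)
}

#' Aging of an Fe(II) stock solution
#'
#' Pseudo-first-order oxidation of a fresh FeSO4 stock by dissolved oxygen
#' at its native pH (near 6.3 for a 1 mM stock): the oxidized fraction is
#' `1 - exp(-k45(pH, room T) * [O2]air * t)`.  Valid only in the pH
#' 6.0-6.5 range where the rate constant is interpolated; outside it the
#' call is rejected rather than extrapolated.
#'
#' @param stock_conc Stock FeSO4 concentration (mol/L).
#' @param ph Stock pH, in \[6.0, 6.5\].
#' @param hours Aging time.
#' @return List with `fraction_oxidized`, and the `fe2`/`fe3`
#'   concentrations remaining in the stock (mol/L).
#' @export
#' @examples
#' age_fe2_stock(1e-3, 6.3, 1)$fraction_oxidized  # ~0.13
age_fe2_stock <- function(stock_conc, ph, hours) {
  stopifnot(stock_conc >= 0, hours >= 0)
  if (ph < 6.0 || ph > 6.5)
    stop("stock pH ", ph, " outside the interpolation range [6.0, 6.5]")
  k <- k_fe2_o2(ph, temperature = 25)
  frac <- 1 - exp(-k * o2_saturation(25) * 3600 * hours)
  list(fraction_oxidized = frac, fe2 = stock_conc * (1 - frac),
       fe3 = stock_conc * frac)
}

#' Simulated DHA dose-response curve
#'
#' Runs the two-coil protocol over a grid of metal concentrations (coil-1
#' basis) and returns the DHA readout for each.
#'
#' @inheritParams run_protocol
#' @param conc_grid Metal concentrations in coil-1 (mol/L).
#' @param ... Further arguments passed to [run_protocol()].
#' @return data.frame with columns `metal_species`, `conc_M`, `dha_uM`,
#'   `ph`.
#' @export
dose_response <- function(mech, metal, conc_grid, ph = 2.8, ...) {
  dha <- vapply(conc_grid, function(cc)
    run_protocol(mech, metal = metal, conc = cc, ph = ph, ...)$readout_uM,
    numeric(1))
  data.frame(metal_species = metal, conc_M = conc_grid, dha_uM = dha,
             ph = ph, stringsAsFactors = FALSE)
}
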