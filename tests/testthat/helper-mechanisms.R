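# shared fixtures, built once per test run

.helper_cache <- new.env(parent = emptyenv())

ascorbate_mech <- function(variant = "catalytic-111") {
  key <- paste0("mech_", variant)
  if (is.null(.helper_cache[[key]]))
    .helper_cache[[key]] <- build_ascorbate_mechanism(variant)
  .helper_cache[[key]]
}

# tiny mechanisms used for closed-form checks
decay_mech <- function(k = 1) {
  parse_mechanism_file(sprintf("R1: A -> B : k=%g", k))
}

# isolated disproportionation equilibrium (tabulated R12 constants)
r12_pair_mech <- function() {
  parse_mechanism_file(c(
    "R12f: 2 A.- + H+ -> AH- + DHA : k=7e4 : orders A.-=2 : base R12",
    "R12b: AH- + DHA -> 2 A.- + H+ : k=4.2e-12 : base R12"
  ))
}

# fast integration settings for protocol-level tests
fastargs <- list(rtol = 1e-6, atol = 1e-14)

fast_protocol <- function(mech, ...) {
  run_protocol(mech, ..., rtol = 1e-6, atol = 1e-14)
}

# small noise-free synthetic copper dataset at one pH (3 concentrations)
small_cu_dataset <- function(ph = 7, sd_add = 0, seed = 1, background = 0) {
  generate_dose_response(ascorbate_mech(), metal = "Cu2",
                         conc_grid = c(2.5, 10, 40) * 1e-6, ph = ph,
                         sd_add = sd_add, background = background,
                         seed = seed, rtol = 1e-6, atol = 1e-14)
}
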