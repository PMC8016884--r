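#!/usr/bin/env Rscript
# Mechanism discrimination: which copper rate law explains the
# dose-response shape?  Fits each candidate law to synthetic data
# generated by the 1:1:1 catalytic mechanism and ranks by best MSE; also
# prints the plateau-versus-linear shape contrast that separates the
# catalytic and redox families.

library(ascorbox)
dir.create("results", showWarnings = FALSE)

mech <- build_ascorbate_mechanism("catalytic-111")
d <- generate_dose_response(mech, "Cu2",
                            conc_grid = c(2.5, 5, 10, 25, 50) * 1e-6,
                            ph = 7, sd_add = 0, background = 0, seed = 1,
                            rtol = 1e-6, atol = 1e-14)

ranking <- compare_rate_laws(
  d,
  variants = list("catalytic-111" = "R17", "cu-halfO2" = "R17",
                  "cu-chloride-law" = "R16", "redox" = "R17"),
  algo = "coord", seed = 1, n_scan = 11, background = 0, precision = 0.05,
  rtol = 1e-6, atol = 1e-14)
write.csv(ranking, "results/rate_law_comparison.csv", row.names = FALSE)
print(ranking, digits = 4)

# shape contrast: catalytic plateau vs unsaturated-redox linearity
grid <- c(2.5, 10, 40) * 1e-6
dc <- dose_response(mech, "Cu2", grid, ph = 7, rtol = 1e-6, atol = 1e-14)
mr <- set_rate_constant(set_rate_constant(build_ascorbate_mechanism("redox"),
                                          "R16", 5), "R17", 5)
dr <- dose_response(mr, "Cu2", grid, ph = 7, rtol = 1e-6, atol = 1e-14)
cat(sprintf("\n16x dose span: catalytic readout grows %.2fx (plateau),\n",
            dc$dha_uM[3] / dc$dha_uM[1]))
cat(sprintf("unsaturated redox grows %.1fx (near linear).\n",
            dr$dha_uM[3] / dr$dha_uM[1]))
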