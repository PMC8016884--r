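#!/usr/bin/env Rscript
# Where does the DHA go?  At neutral pH a fair share of the DHA formed in
# the 20-minute first coil is destroyed again before derivatization --
# mostly by hydrolysis to DKG.  This script quantifies the degradation
# share for iron and copper at both assay pHs.

library(ascorbox)
dir.create("results", showWarnings = FALSE)

mech <- build_ascorbate_mechanism("catalytic-111")
cases <- expand.grid(metal = c("Fe3", "Cu2"), ph = c(2.8, 7),
                     stringsAsFactors = FALSE)

rows <- lapply(seq_len(nrow(cases)), function(i) {
  res <- integrate_segment(
    mech, coil1_conditions(cases$metal[i], 2.5e-6, ph = cases$ph[i]),
    ledger = TRUE)
  b <- dha_budget(res)
  data.frame(metal = cases$metal[i], ph = cases$ph[i],
             dha_formed_uM = b$produced * 1e6,
             dha_degraded_uM = b$degraded * 1e6,
             degraded_pct = 100 * b$fraction_degraded)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/dha_budget.csv", row.names = FALSE)
print(tab, digits = 3)

cat("\nDegradation is negligible at pH 2.8 (DHA is stable in acid) but\n",
    "reaches tens of percent at pH 7, dominated by hydrolysis; the first\n",
    "coil has no oPDA, so nothing protects DHA there.\n")
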