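#!/usr/bin/env Rscript
# How much ascorbic acid do the metals oxidize directly, versus the ROS
# they generate?  Simulates the pH 2.8 first reaction coil over a range of
# Fe(II) doses (10% pre-oxidized stock) and attributes AH2/AH- loss to the
# catalytic rows (R14-R17) versus the radical rows (R4-R9).

library(ascorbox)
dir.create("results", showWarnings = FALSE)

mech <- build_ascorbate_mechanism("catalytic-111")
concs <- c(2.5, 10, 50, 100, 200) * 1e-6

rows <- lapply(concs, function(cc) {
  res <- integrate_segment(mech, coil1_conditions("Fe2", cc, ph = 2.8),
                           ledger = TRUE)
  pr <- pathway_ratio(res)
  data.frame(fe2_nominal_uM = cc * 1e6,
             catalytic_uM = pr$catalytic * 1e6,
             ros_uM = pr$ros * 1e6,
             ratio = pr$ratio)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/pathway_attribution.csv", row.names = FALSE)
print(tab, digits = 3)

cat(sprintf(
  "\nThe catalytic:ROS ratio falls from %.1f at %.1f uM Fe(II) to %.2f at %g uM:\n",
  tab$ratio[1], tab$fe2_nominal_uM[1], tab$ratio[nrow(tab)],
  tab$fe2_nominal_uM[nrow(tab)]),
  "at low Fe(II) the small pre-oxidized Fe(III) fraction does nearly all\n",
  "the oxidation, while at high Fe(II) the Fenton conversion of the\n",
  "catalytically produced H2O2 makes the radical channel competitive.\n")

# Fe(III)-only runs for contrast: ROS never get started
r3 <- integrate_segment(mech, coil1_conditions("Fe3", 2.5e-6, ph = 2.8),
                        ledger = TRUE)
cat(sprintf("Fe(III)-only 2.5 uM: catalytic/ROS = %.3g (>= 4 orders).\n",
            pathway_ratio(r3)$ratio))
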