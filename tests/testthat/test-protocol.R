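test_that("flow mixing conserves the molar flux of every species", {
  s1 <- stream(1.1, c(AH2 = 2e-4, "Cl-" = 3.2e-3))
  s2 <- stream(1.1, c("Cu2+" = 5e-6, "SO42-" = 5e-6))
  mx <- mix_streams(list(s1, s2))
  expect_equal(mx$flow, 2.2)
  expect_equal(mx$composition[["AH2"]], 1e-4, tolerance = 1e-12)
  expect_equal(mx$composition[["Cu2+"]], 2.5e-6, tolerance = 1e-12)
  # molar flux across the junction is unchanged
  for (sp in names(mx$composition)) {
    inflow <- s1$flow * (if (sp %in% names(s1$composition)) s1$composition[[sp]] else 0) +
      s2$flow * (if (sp %in% names(s2$composition)) s2$composition[[sp]] else 0)
    expect_equal(mx$flow * mx$composition[[sp]], inflow, tolerance = 1e-12)
  }
  # unequal flows weight accordingly
  mx2 <- mix_streams(list(stream(2.2, c(A = 1)), stream(1.1, c(A = 4))))
  expect_equal(mx2$composition[["A"]], 2)
})

test_that("coil-1 conditions encode the experiment's dosing rules", {
  c1 <- coil1_conditions("Fe2", 10e-6, ph = 2.8)
  expect_equal(c1$initial[["AH2"]], 1e-4)
  expect_equal(c1$initial[["Fe2+"]], 9e-6)   # 10% pre-oxidized stock
  expect_equal(c1$initial[["Fe3+"]], 1e-6)
  expect_equal(c1$initial[["SO42-"]], 10e-6)
  expect_equal(c1$initial[["Cl-"]], 1.6e-3)  # HCl pH adjustment
  expect_equal(c1$temperature, 37)
  expect_equal(c1$duration, 1200)
  c7 <- coil1_conditions("Fe3", 10e-6, ph = 7)
  expect_false("Cl-" %in% names(c7$initial))
  expect_equal(c7$initial[["SO42-"]], 15e-6)  # Fe2(SO4)3 counter-ions
  expect_error(coil1_conditions("Zn2", 1e-6), "unsupported metal")
})

test_that("Fe(II) stock aging follows pseudo-first-order oxidation", {
  # ~13%/h at the stock's native pH 6.3
  a <- age_fe2_stock(1e-3, 6.3, 1)
  expect_equal(a$fraction_oxidized, 0.13, tolerance = 0.05)
  # closed form at pH 6.0: 1 - exp(-0.11 * [O2](25C) * 3600)
  b <- age_fe2_stock(1e-3, 6.0, 1)
  expect_equal(b$fraction_oxidized, 1 - exp(-0.11 * 2.58e-4 * 3600),
               tolerance = 1e-10)
  expect_equal(b$fraction_oxidized, 0.097, tolerance = 0.01)
  expect_equal(age_fe2_stock(1e-3, 6.3, 0)$fraction_oxidized, 0)
  expect_equal(a$fe2 + a$fe3, 1e-3)
  # no extrapolation outside the interpolation range
  expect_error(age_fe2_stock(1e-3, 5.5, 1), "outside")
  expect_error(age_fe2_stock(1e-3, 7.0, 1), "outside")
})

test_that("metal-free runs read out only the background", {
  mech <- ascorbate_mech()
  p <- fast_protocol(mech, metal = "none", ph = 2.8, background = 2.8e-6)
  expect_equal(p$readout_uM, 2.8, tolerance = 0.01)
  p0 <- fast_protocol(mech, metal = "none", ph = 2.8)
  expect_lt(p0$readout_uM, 1e-3)
})

test_that("oPDA derivatization is essentially complete within coil 2", {
  mech <- ascorbate_mech()
  a <- fast_protocol(mech, "Cu2", 2.5e-6, ph = 7)
  b <- fast_protocol(mech, "Cu2", 2.5e-6, ph = 7, coil2_duration = 1200)
  expect_lt(abs(b$readout_uM - a$readout_uM) / a$readout_uM, 0.02)
  # nearly all DHA leaves as the adduct
  fin <- final_state(a$coil2)
  expect_gt(fin[["DHAoPDA"]] / (fin[["DHAoPDA"]] + fin[["DHA"]]), 0.95)
})

test_that("readout bases differ exactly by the coil-2 dilution", {
  mech <- ascorbate_mech()
  a <- fast_protocol(mech, "Fe3", 5e-6, ph = 2.8, readout_basis = "coil1")
  b <- fast_protocol(mech, "Fe3", 5e-6, ph = 2.8, readout_basis = "coil2")
  expect_equal(b$readout_uM / a$readout_uM, 2 / 3, tolerance = 1e-9)
})

test_that("Fe(II) produces roughly a sixth of the Fe(III) response", {
  mech <- ascorbate_mech()
  f2 <- fast_protocol(mech, "Fe2", 2.5e-6, ph = 2.8)$readout_uM
  f3 <- fast_protocol(mech, "Fe3", 2.5e-6, ph = 2.8)$readout_uM
  expect_gt(f2 / f3, 1 / 20)   # order-of-magnitude agreement
  expect_lt(f2 / f3, 1 / 3)
})

test_that("Fe(III) dose-response curves rise strictly at acidic pH", {
  mech <- ascorbate_mech()
  d <- dose_response(mech, "Fe3", c(2.5, 10, 50) * 1e-6, ph = 2.8,
                     rtol = 1e-6, atol = 1e-14)
  expect_true(all(diff(d$dha_uM) > 0))
  expect_equal(names(d), c("metal_species", "conc_M", "dha_uM", "ph"))
})

test_that("the catalytic variant plateaus where an unsaturated redox variant is linear", {
  grid <- c(2.5, 10, 40) * 1e-6
  dc <- dose_response(ascorbate_mech(), "Cu2", grid, ph = 7,
                      rtol = 1e-6, atol = 1e-14)
  # redox mechanism with its constant scaled into the unsaturated regime
  mr <- set_rate_constant(set_rate_constant(ascorbate_mech("redox"), "R16", 5),
                          "R17", 5)
  dr <- dose_response(mr, "Cu2", grid, ph = 7, rtol = 1e-6, atol = 1e-14)
  # a 16x concentration span: linear response scales ~16x, the
  # oxygen-limited catalytic response barely moves
  expect_lt(dc$dha_uM[3] / dc$dha_uM[1], 2)
  expect_gt(dr$dha_uM[3] / dr$dha_uM[1], 8)
})
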