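test_that("the full mechanism encodes the catalytic family with its tabulated constants", {
  mech <- ascorbate_mech()
  expect_s3_class(mech, "aa_mechanism")

  # lumped metal groups expand into one instance per complex, sharing one k
  k14 <- get_rate_constant(mech, "R14")
  k15 <- get_rate_constant(mech, "R15")
  k16 <- get_rate_constant(mech, "R16")
  k17 <- get_rate_constant(mech, "R17")
  expect_length(k14, 6)
  expect_length(k15, 6)
  expect_length(k16, 5)
  expect_length(k17, 5)
  expect_true(all(k14 == 5.7e4))
  expect_true(all(k15 == 4.7e4))
  expect_true(all(k16 == 7.7e4))
  expect_true(all(k17 == 2.8e6))

  # report-only validation is clean on the full network
  v <- validate_mechanism(mech)
  expect_length(v$errors, 0)
  expect_true(all(abs(v$moiety[, c("iron", "copper", "ascorbate")]) < 1e-12))

  # deterministic build
  mech2 <- build_ascorbate_mechanism()
  expect_identical(reaction_ids(mech), reaction_ids(mech2))
  expect_equal(mech$reactions, mech2$reactions)
})

test_that("reversible rows are split consistently with tabulated equilibrium constants", {
  mech <- ascorbate_mech()
  ids <- reaction_ids(mech)
  kf <- function(id) mech$reactions[[match(paste0(id, "f"), ids)]]$k
  kr <- function(id) mech$reactions[[match(paste0(id, "b"), ids)]]$k
  # rows printing all of kf, kr, Keq agree to 1%
  triples <- c(R12 = 1.67e16, R13 = 2.1e20, R34 = 1e-14, R35 = 1.26e-12,
               R36 = 1.58e-5, R44 = 1.39, R52 = 3.1e-3, R53 = 2e-4)
  for (nm in names(triples)) {
    expect_lt(abs(kf(nm) / kr(nm) - triples[[nm]]) / triples[[nm]], 0.01)
  }
  # the two disproportionation equilibria are linked through the first
  # acid dissociation constant: K13 = K12 / Ka1
  expect_lt(abs((1.67e16 / 7.94e-5) - 2.1e20) / 2.1e20, 0.01)

  # Keq-only rows: forward k = Keq * fast backward default
  expect_equal(kf("R38") / kr("R38"), 6.11e-3, tolerance = 1e-12)
  expect_equal(kr("R38"), mech$fast_kr)
})

test_that("split_equilibrium resolves and cross-checks rate-constant triples", {
  # tabulated pair reproduces the tabulated equilibrium constant
  expect_equal(split_equilibrium(kf = 7e4, kr = 4.2e-12)$Keq, 1.67e16,
               tolerance = 0.005)
  expect_equal(split_equilibrium(kf = 1, kr = 1)$Keq, 1)
  # Keq-only rows get the documented fast default
  s <- split_equilibrium(Keq = 6.11e-3)
  expect_equal(s$kr, 1e10)
  expect_equal(s$kf, 6.11e7)
  # mutually inconsistent triples beyond 5% are rejected
  expect_error(split_equilibrium(kf = 1, kr = 1, Keq = 2), "inconsistent")
  expect_error(split_equilibrium(), "at least one")
})

test_that("proton bookkeeping and footnoted values follow the tables", {
  mech <- ascorbate_mech()
  ids <- reaction_ids(mech)
  rx <- function(id) mech$reactions[[match(id, ids)]]
  # net proton consumption is rewritten onto the reactant side with zero
  # kinetic order, preserving the tabulated rate expression
  r11 <- rx("R11")
  expect_true("H+" %in% names(r11$reactants))
  expect_false("H+" %in% names(r11$orders))
  r15 <- rx("R15_Fe3+")
  expect_true("H+" %in% names(r15$reactants))
  expect_false("H+" %in% names(r15$orders))
  # backward halves of acid-base equilibria do carry first-order [H+]
  expect_equal(rx("R1b")$orders[["H+"]], 1)
  # upper-limit cells use the tabulated bound
  expect_equal(rx("R47")$k, 1e3)
  expect_equal(rx("R80")$k, 100)
  # R77 is species-resolved within the copper lump
  expect_equal(rx("R77_Cu2+")$k, 1)
  expect_equal(rx("R77_CuCl+")$k, 70)
  expect_equal(rx("R77_CuCl2")$k, 70)
  # R61 shares the Fenton constant of R60
  expect_equal(rx("R61")$k, rx("R60")$k)
  expect_equal(rx("R60")$k, 55)
})

test_that("mechanism variants alter only the metal-ascorbate step", {
  redox <- ascorbate_mech("redox")
  # no redox metal step produces hydrogen peroxide directly
  for (r in redox$reactions) {
    if ("redox" %in% r$tags) expect_false("H2O2" %in% names(r$products))
  }
  # the metal is reduced instead of regenerated
  r16 <- redox$reactions[[match("R16_Cu2+", reaction_ids(redox))]]
  expect_true("Cu+" %in% names(r16$products))

  half <- ascorbate_mech("cu-halfO2")
  r17 <- half$reactions[[match("R17_Cu2+", reaction_ids(half))]]
  expect_equal(r17$orders[["O2"]], 0.5)
  expect_equal(r17$k, 1.2e5)

  chlor <- ascorbate_mech("cu-chloride-law")
  r16a <- chlor$reactions[[match("R16a_Cu2+", reaction_ids(chlor))]]
  expect_equal(sort(r16a$pool), sort(c("AH2", "AH-")))
  expect_equal(r16a$pool_exp, -0.5)
  expect_false("R17" %in% reaction_ids(chlor, base = TRUE))

  mixed <- ascorbate_mech("catalytic+redox")
  base <- reaction_ids(mixed, base = TRUE)
  expect_true(all(c("R16", "R17", "R16r", "R17r") %in% base))

  expect_error(build_ascorbate_mechanism("no-such-law"), "unknown")
  # every variant stays moiety balanced
  for (m in list(redox, half, chlor, mixed)) {
    expect_length(validate_mechanism(m)$errors, 0)
  }
})

test_that("condition-dependent rate constants follow their pH/temperature rules", {
  expect_equal(k_fe2_o2(2.8, 37), 1e-4)
  expect_equal(k_fe2_o2(2.8, 25), 1e-5)
  expect_equal(k_fe2_o2(7, 37), 3.9)
  expect_equal(k_fe2_o2(7, 25), 0.39)
  expect_equal(k_fe2_o2(6.0, 25), 0.11)
  expect_equal(k_fe2_o2(6.5, 25), 0.17)
  expect_equal(k_fe2_o2(6.25, 25), 0.14)  # linear between the anchors

  mech <- ascorbate_mech()
  ids <- reaction_ids(mech)
  # DHA hydrolysis: off at low pH, full speed at neutral, linear ramp
  k_low <- resolve_rate_constants(mech, 2.8, 37)[["R20"]]
  k_mid <- resolve_rate_constants(mech, 5, 37)[["R20"]]
  k_high <- resolve_rate_constants(mech, 7, 37)[["R20"]]
  expect_equal(k_low, 0)
  expect_equal(k_mid, 5.8e-4 * 0.5)
  expect_equal(k_high, 5.8e-4)
  expect_equal(resolve_rate_constants(mech, 2.8, 37)[["R45"]], 1e-4)
})
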