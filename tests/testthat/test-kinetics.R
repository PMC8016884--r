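test_that("integration reproduces first-order decay and handles zero duration", {
  m <- decay_mech(k = 1)
  cond <- segment_conditions(ph = 7, duration = 1, initial = c(A = 1))
  for (eng in c("compiled", "r")) {
    res <- integrate_segment(m, cond, ledger = TRUE, n_out = 5, engine = eng)
    expect_equal(final_state(res)[["A"]], exp(-1), tolerance = 1e-7)
    expect_equal(final_state(res)[["B"]], 1 - exp(-1), tolerance = 1e-7)
  }
  # species-state and extent-state layouts agree
  r0 <- integrate_segment(m, cond, ledger = FALSE)
  expect_equal(final_state(r0)[["A"]], exp(-1), tolerance = 1e-7)
  # zero-duration segment returns the initial state unchanged
  rz <- integrate_segment(m, segment_conditions(duration = 0, initial = c(A = 1)))
  expect_equal(final_state(rz)[["A"]], 1)
  expect_equal(max(rz$times), 0)
})

test_that("isolated equilibria relax to their tabulated constants", {
  # disproportionation pair: the tabulated-convention constant
  # [AH-][DHA]/[A.-]^2 = 1.67e16 is a stationary point of the pair (its
  # backward constant is so small that full relaxation from arbitrary
  # states takes geological time, so stationarity is the meaningful check)
  m <- r12_pair_mech()
  aeq <- sqrt(5e-7 * 5e-7 / 1.67e16)
  cond <- segment_conditions(ph = 7.4, duration = 1e4,
                             initial = c("AH-" = 5e-7, DHA = 5e-7,
                                         "A.-" = aeq))
  res <- integrate_segment(m, cond, ledger = FALSE, atol = 1e-22)
  fin <- final_state(res)
  ratio <- fin[["AH-"]] * fin[["DHA"]] / fin[["A.-"]]^2
  expect_lt(abs(ratio - 1.67e16) / 1.67e16, 1e-3)
  # displaced from equilibrium, the net rate points back toward it
  a <- assemble_rhs(m, cond)
  up <- a$rhs(0, c("AH-" = 5e-7, DHA = 5e-7, "A.-" = 10 * aeq,
                   "H+" = 10^-7.4, "OH-" = 10^-6.6, H2O = 1)[a$species])
  expect_lt(up[["A.-"]], 0)

  # Keq-only hydrolysis pair with the fast default backward constant:
  # [Y][H+]/[X] relaxes to Keq = 6.11e-3
  ks <- split_equilibrium(Keq = 6.11e-3)
  m2 <- parse_mechanism_file(c(
    sprintf("Rf: X -> Y + H+ : k=%.10g", ks$kf),
    sprintf("Rb: Y + H+ -> X : k=%.10g", ks$kr)
  ))
  ph <- 2.8
  cond2 <- segment_conditions(ph = ph, duration = 1e-5, initial = c(X = 1e-4))
  res2 <- integrate_segment(m2, cond2, ledger = FALSE, atol = 1e-20)
  fin2 <- final_state(res2)
  ratio2 <- fin2[["Y"]] * 10^(-ph) / fin2[["X"]]
  expect_lt(abs(ratio2 - 6.11e-3) / 6.11e-3, 1e-3)
})

test_that("hydroperoxyl self-reaction follows its closed-form solution", {
  # 2 HO2. -> O2 + H2O2 with rate k[HO2.]^2:
  # c(t) = c0 / (1 + 2 k c0 t), H2O2 = (c0 - c)/2
  k <- 8.3e5; c0 <- 1e-6; tt <- 10
  m <- parse_mechanism_file(sprintf("R31: 2 HO2. -> O2 + H2O2 : k=%g", k))
  cond <- segment_conditions(ph = 7, duration = tt, initial = c("HO2." = c0))
  res <- integrate_segment(m, cond, ledger = FALSE)
  c_exact <- c0 / (1 + 2 * k * c0 * tt)
  expect_lt(abs(final_state(res)[["HO2."]] - c_exact) / c_exact, 1e-3)
  h2o2_exact <- (c0 - c_exact) / 2
  expect_lt(abs(final_state(res)[["H2O2"]] - h2o2_exact) / h2o2_exact, 1e-3)
})

test_that("compiled and R rate evaluations agree on the full mechanism", {
  mech <- ascorbate_mech()
  cond <- coil1_conditions("Fe2", 2.5e-6, ph = 2.8)
  a <- assemble_rhs(mech, cond)
  cm <- ascorbox:::.compile_mechanism(mech, cond, mode = 0L)
  .Call("C_mech_load", cm, PACKAGE = "ascorbox")
  set.seed(42)
  for (rep in 1:5) {
    # random strictly positive state spanning many magnitudes
    conc <- setNames(10^runif(length(a$species), -12, -3), a$species)
    conc[c("H+", "OH-", "H2O")] <- cm$c0_named[c("H+", "OH-", "H2O")]
    ev <- .Call("C_mech_eval", unname(conc), PACKAGE = "ascorbox")
    dR <- a$rhs(0, conc)
    scale <- pmax(abs(dR), max(abs(dR)) * 1e-8)
    expect_lt(max(abs(ev$ydot - dR) / scale), 1e-6)
    rR <- a$rates(conc)
    expect_lt(max(abs(ev$rates - rR) / pmax(rR, max(rR) * 1e-10)), 1e-6)
  }
})

test_that("the flux ledger is exactly consistent with concentration changes", {
  mech <- ascorbate_mech()
  cond <- coil1_conditions("Fe2", 2.5e-6, ph = 2.8, duration = 300)
  res <- integrate_segment(mech, cond, ledger = TRUE, n_out = 6)
  nmat <- ascorbox:::.extent_matrix(mech)
  free <- setdiff(colnames(res$conc), c("H+", "OH-", "H2O"))
  for (i in seq_along(res$times)) {
    dc <- res$conc[i, free] - res$conc[1, free]
    lhs <- drop(nmat[free, ] %*% res$extents[i, ])
    expect_lt(max(abs(dc - lhs)), 1e-15)
  }
  # and the two state layouts agree on the final concentrations
  res0 <- integrate_segment(mech, cond, ledger = FALSE)
  keyspecies <- c("AH2", "AH-", "DHA", "O2", "H2O2", "Fe2+", "Fe3+")
  for (s in keyspecies) {
    expect_equal(final_state(res)[[s]], final_state(res0)[[s]],
                 tolerance = 1e-5)
  }
})

test_that("stiff integration matches an independent implementation at tighter tolerance", {
  mech <- ascorbate_mech()
  cond <- coil1_conditions("Fe3", 2.5e-6, ph = 2.8)
  ra <- integrate_segment(mech, cond, ledger = FALSE)
  rb <- integrate_segment(mech, cond, ledger = FALSE, engine = "r",
                          rtol = 1e-10, atol = 1e-18)
  dha_a <- final_state(ra)[["DHA"]]
  dha_b <- final_state(rb)[["DHA"]]
  expect_lt(abs(dha_a - dha_b) / dha_b, 0.10)
})

test_that("no-metal coils form essentially no DHA", {
  mech <- ascorbate_mech()
  cond <- coil1_conditions("none", 0, ph = 2.8)
  res <- integrate_segment(mech, cond, ledger = FALSE)
  expect_lt(final_state(res)[["DHA"]], 1e-9)
})

test_that("conserved moieties drift only at integration-error level", {
  mech <- ascorbate_mech()
  fe <- integrate_segment(mech, coil1_conditions("Fe2", 2.5e-6, ph = 2.8,
                                                 duration = 600),
                          ledger = TRUE)
  dr <- conservation_report(fe)
  expect_lt(dr[["iron"]], 1e-6)
  expect_lt(dr[["ascorbate"]], 1e-4)
  expect_lt(dr[["sulfate"]], 1e-6)
  cu <- integrate_segment(mech, coil1_conditions("Cu2", 2.5e-6, ph = 7,
                                                 duration = 600),
                          ledger = TRUE)
  expect_lt(conservation_report(cu)[["copper"]], 1e-6)
})

test_that("DHA formation is monotone in Fe(III) while oxygen is unlimiting", {
  mech <- ascorbate_mech()
  dha <- vapply(c(0, 10, 50) * 1e-6, function(cc) {
    final_state(integrate_segment(mech, coil1_conditions("Fe3", cc, ph = 2.8),
                                  ledger = FALSE))[["DHA"]]
  }, numeric(1))
  expect_true(all(diff(dha) > 0))
})

test_that("tightening tolerances tenfold leaves the DHA readout stable", {
  mech <- ascorbate_mech()
  cond <- coil1_conditions("Fe3", 2.5e-6, ph = 2.8)
  a <- final_state(integrate_segment(mech, cond, ledger = FALSE,
                                     rtol = 1e-8, atol = 1e-16))[["DHA"]]
  b <- final_state(integrate_segment(mech, cond, ledger = FALSE,
                                     rtol = 1e-9, atol = 1e-17))[["DHA"]]
  expect_lt(abs(a - b) / b, 0.005)
})

test_that("negative excursions stay at integrator noise level", {
  mech <- ascorbate_mech()
  res <- integrate_segment(mech, coil1_conditions("Cu2", 25e-6, ph = 7),
                           ledger = FALSE)
  expect_gt(min(res$conc), -1e-10)
})

test_that("dynamic pH mode integrates protons explicitly", {
  mech <- ascorbate_mech()
  cond <- segment_conditions(ph = 3, duration = 10, initial = c(AH2 = 1e-4),
                             ph_mode = "dynamic")
  res <- integrate_segment(mech, cond, ledger = FALSE, n_out = 5)
  h <- res$conc[, "H+"]
  expect_true(all(is.finite(h)) && all(h > 0))
  # ascorbic acid dissociation releases protons into an unbuffered solution
  expect_gt(final_state(res)[["H+"]], 1e-3)
})

test_that("species outside every reaction are retained as constants", {
  m <- parse_mechanism_file(c(
    "species A : init=0", "species B : init=0", "species C : init=0",
    "R1: A -> B : k=1"
  ))
  expect_warning(assemble_rhs(m, segment_conditions(ph = 7), warn = TRUE),
                 "retained as constant")
  cond <- segment_conditions(ph = 7, duration = 1, initial = c(A = 1, C = 0.5))
  res <- integrate_segment(m, cond, ledger = FALSE)
  expect_equal(final_state(res)[["C"]], 0.5)
})

test_that("segment trajectories and ledgers export to CSV/JSON", {
  m <- decay_mech()
  res <- integrate_segment(m, segment_conditions(duration = 1,
                                                 initial = c(A = 1)),
                           ledger = TRUE, n_out = 4)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_segment_csv(res, csv)
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(back$time_s, res$times)
  expect_equal(back$A, unname(res$conc[, "A"]), tolerance = 1e-12)
  write_ledger_json(res, js)
  led <- jsonlite::fromJSON(js)
  expect_equal(led$R1, unname(res$extents[nrow(res$extents), "R1"]),
               tolerance = 1e-12)
  unlink(c(csv, js))
})
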