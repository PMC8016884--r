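#' @useDynLib ascorbox, .registration = TRUE
#' @importFrom stats setNames rnorm runif approx
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- equation parsing -------------------------------------------------------

# "Fe3+ + 2 SO42- -> Fe(SO4)2-" sides are split on " + "; a leading number
# followed by a space is a stoichiometric coefficient.
.parse_side <- function(text) {
  text <- trimws(text)
  if (text == "" || text == "0") return(setNames(numeric(0), character(0)))
  parts <- strsplit(text, " + ", fixed = TRUE)[[1]]
  nm <- character(0); st <- numeric(0)
  for (p in parts) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([0-9]*\\.?[0-9]+)\\s+(.+)$", p))[[1]]
    if (length(m) == 3) {
      coef <- as.numeric(m[2]); sp <- m[3]
    } else {
      coef <- 1; sp <- p
    }
    if (sp == "" || grepl("^[0-9.]+$", sp))
      stop("malformed stoichiometry term '", p, "'")
    if (sp %in% nm) {
      st[match(sp, nm)] <- st[match(sp, nm)] + coef
    } else {
      nm <- c(nm, sp); st <- c(st, coef)
    }
  }
  setNames(st, nm)
}

.parse_equation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("equation must contain '->': ", eq)
  list(reactants = .parse_side(sides[1]), products = .parse_side(sides[2]))
}

.format_side <- function(st) {
  if (length(st) == 0) return("0")
  paste(ifelse(st == 1, names(st), paste(format(st, trim = TRUE), names(st))),
        collapse = " + ")
}

# ---- reaction constructor ---------------------------------------------------

.new_reaction <- function(id, base_id, reactants, products, orders, k,
                          kspec = "fixed", pool = NULL, pool_exp = 0,
                          tags = character(0), note = "") {
  stopifnot(is.character(id), length(id) == 1, k >= 0 || is.na(k))
  if (any(orders < 0)) stop("negative kinetic order in ", id)
  if (length(reactants) && any(reactants <= 0)) stop("non-positive stoichiometry in ", id)
  if (length(products) && any(products <= 0)) stop("non-positive stoichiometry in ", id)
  structure(list(id = id, base_id = base_id, reactants = reactants,
                 products = products, orders = orders, k = k, kspec = kspec,
                 pool = pool, pool_exp = pool_exp, tags = tags, note = note),
            class = "aa_reaction")
}

# Build one irreversible reaction from an equation string.
# `minus_h` rewrites net proton consumption ("... - H+" products in the
# source tables) as an H+ reactant with kinetic order zero, so the tabulated
# rate expression is preserved while protons balance.
# Default orders: reactant stoichiometry, except H2O (constant activity,
# order 0) and minus_h protons (order 0).
.rx <- function(id, eq, k, base_id = id, minus_h = 0, orders = NULL,
                kspec = "fixed", pool = NULL, pool_exp = 0,
                tags = character(0), note = "") {
  pe <- .parse_equation(eq)
  reac <- pe$reactants; prod <- pe$products
  if (minus_h > 0) {
    reac["H+"] <- (if ("H+" %in% names(reac)) reac[["H+"]] else 0) + minus_h
  }
  if (is.null(orders)) {
    orders <- reac
    orders[names(orders) == "H2O"] <- 0
    if (minus_h > 0) orders["H+"] <- 0
  }
  orders <- orders[orders > 0]
  .new_reaction(id, base_id, reac, prod, orders, k, kspec = kspec,
                pool = pool, pool_exp = pool_exp, tags = tags, note = note)
}

# ---- equilibrium handling ---------------------------------------------------

#' Split a reversible reaction into forward and backward rate constants
#'
#' Resolves the (kf, kr, Keq) triple of a reversible reaction row into the
#' two irreversible rate constants actually integrated.  With only `Keq`
#' supplied, the backward constant takes the fast default `default_kr` and
#' the forward constant is `Keq * default_kr`; with `kf` and `kr` supplied,
#' `Keq` is derived (and cross-checked if also tabulated).
#'
#' @param kf,kr Forward/backward rate constants (units per the reaction's
#'   molecularity); `NA` if not known.
#' @param Keq Equilibrium constant `kf / kr`; `NA` if not known.
#' @param default_kr Backward rate constant assumed for Keq-only rows
#'   (treated as a fast equilibrium).
#' @param tol_warn,tol_error Relative Keq-consistency thresholds: beyond
#'   `tol_warn` a warning is raised, beyond `tol_error` the triple is
#'   rejected as inconsistent.
#' @return List with elements `kf`, `kr`, `Keq`.
#' @export
#' @examples
#' split_equilibrium(kf = 7e4, kr = 4.2e-12)$Keq   # 1.67e16
#' split_equilibrium(Keq = 6.11e-3)$kf             # 6.11e7
split_equilibrium <- function(kf = NA, kr = NA, Keq = NA, default_kr = 1e10,
                              tol_warn = 0.01, tol_error = 0.05) {
  have_kf <- is.finite(kf); have_kr <- is.finite(kr); have_keq <- is.finite(Keq)
  if (!have_kf && !have_kr && !have_keq)
    stop("at least one of kf, kr or Keq must be supplied")
  if (have_kf && have_kr) {
    ratio <- kf / kr
    if (have_keq) {
      rel <- abs(ratio - Keq) / Keq
      if (rel > tol_error)
        stop(sprintf("kf/kr = %.4g inconsistent with Keq = %.4g (%.1f%%)",
                     ratio, Keq, 100 * rel))
      if (rel > tol_warn)
        warning(sprintf("kf/kr deviates from tabulated Keq by %.2f%%", 100 * rel))
    }
    return(list(kf = kf, kr = kr, Keq = ratio))
  }
  if (have_keq && !have_kf && !have_kr)
    return(list(kf = Keq * default_kr, kr = default_kr, Keq = Keq))
  if (have_keq && have_kf) return(list(kf = kf, kr = kf / Keq, Keq = Keq))
  if (have_keq && have_kr) return(list(kf = Keq * kr, kr = kr, Keq = Keq))
  stop("cannot resolve an equilibrium from a single rate constant without Keq")
}

# Emit the forward/backward pair for one reversible row.  Backward kinetic
# orders are the product stoichiometries (H+ included: that is what makes
# acid-base speciation pH dependent), except H2O.
.eqm <- function(id, eq, kf = NA, kr = NA, Keq = NA, default_kr = 1e10,
                 minus_h = 0, tags = character(0), note = "") {
  ks <- split_equilibrium(kf, kr, Keq, default_kr = default_kr)
  pe <- .parse_equation(eq)
  fwd <- .rx(paste0(id, "f"), eq, ks$kf, base_id = id, minus_h = minus_h,
             tags = c(tags, "equilibrium-forward"), note = note)
  bwd_reac <- pe$products
  bwd_prod <- pe$reactants
  if (minus_h > 0) bwd_prod["H+"] <- (if ("H+" %in% names(bwd_prod)) bwd_prod[["H+"]] else 0) + minus_h
  orders <- bwd_reac
  orders[names(orders) == "H2O"] <- 0
  orders <- orders[orders > 0]
  bwd <- .new_reaction(paste0(id, "b"), id, bwd_reac, bwd_prod, orders, ks$kr,
                       tags = c(tags, "equilibrium-backward"), note = note)
  list(fwd, bwd)
}

# Instantiate a reaction template over a lumped metal group.  "{M}" in the
# equation is replaced by each member; transformed complexes release their
# ligands (extra products) so that sulfate/chloride moieties balance.
.lump <- function(id_prefix, members, eq_template, k, release = TRUE,
                  minus_h = 0, tags = character(0), note = "",
                  k_by_member = NULL, base_id = id_prefix) {
  out <- list()
  for (m in members) {
    eq <- gsub("{M}", m, eq_template, fixed = TRUE)
    extra <- if (release) .released_ligands(m) else c()
    pe <- .parse_equation(eq)
    prod <- pe$products
    for (lig in names(extra)) {
      prod[lig] <- (if (lig %in% names(prod)) prod[[lig]] else 0) + extra[[lig]]
    }
    km <- if (!is.null(k_by_member)) k_by_member[[m]] else k
    r <- .rx(paste0(id_prefix, "_", m),
             paste(.format_side(pe$reactants), "->", .format_side(prod)),
             km, base_id = base_id, minus_h = minus_h, tags = tags, note = note)
    out <- c(out, list(r))
  }
  out
}

# ---- mechanism object -------------------------------------------------------

.new_mechanism <- function(species, reactions, variant, fast_kr,
                           metadata = list()) {
  sp <- species$name
  for (r in reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products),
                         names(r$orders), r$pool), sp)
    if (length(unknown))
      stop("reaction ", r$id, " references undeclared species: ",
           paste(unknown, collapse = ", "))
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(species = species, reactions = reactions, variant = variant,
                 fast_kr = fast_kr, metadata = metadata),
            class = "aa_mechanism")
}

#' @export
print.aa_mechanism <- function(x, ...) {
  cat(sprintf("<aa_mechanism> variant=%s: %d species, %d irreversible reactions\n",
              x$variant, nrow(x$species), length(x$reactions)))
  invisible(x)
}

#' Reaction ids of a mechanism
#' @param mech An `aa_mechanism`.
#' @param base Return base (table-row) ids instead of instance ids.
#' @return Character vector.
#' @export
reaction_ids <- function(mech, base = FALSE) {
  f <- if (base) "base_id" else "id"
  vapply(mech$reactions, `[[`, character(1), f)
}

#' Set the rate constant of a table row
#'
#' Assigns `k` to every irreversible reaction instance whose base id matches
#' (all members of a lumped metal group share the one constant).  Backward
#' halves of equilibria are excluded.
#'
#' @param mech An `aa_mechanism`.
#' @param id Base reaction id, e.g. `"R16"`.
#' @param k New rate constant (>= 0).
#' @return The modified mechanism.
#' @export
set_rate_constant <- function(mech, id, k) {
  stopifnot(k >= 0)
  hit <- FALSE
  for (i in seq_along(mech$reactions)) {
    r <- mech$reactions[[i]]
    if (r$base_id == id && !("equilibrium-backward" %in% r$tags)) {
      mech$reactions[[i]]$k <- k
      mech$reactions[[i]]$kspec <- "fixed"
      hit <- TRUE
    }
  }
  if (!hit) stop("no reaction with base id ", id)
  mech
}

#' Get the rate constant(s) of a table row
#' @inheritParams set_rate_constant
#' @return Named numeric vector of instance rate constants.
#' @export
get_rate_constant <- function(mech, id) {
  out <- c()
  for (r in mech$reactions) {
    if (r$base_id == id && !("equilibrium-backward" %in% r$tags))
      out[r$id] <- r$k
  }
  if (!length(out)) stop("no reaction with base id ", id)
  out
}

# ---- the full mechanism ----------------------------------------------------

#' Build the full ascorbate oxidation mechanism
#'
#' Encodes the complete aqueous reaction network: ascorbate acid-base and
#' radical chemistry, the three DHA degradation channels and the oPDA
#' derivatization step, ROS interconversions, iron and copper speciation
#' equilibria, Fenton chemistry, and HEPES/benzoate/phosphate chemistry for
#' hydroxyl-radical scenarios.  The metal-ascorbate step is selected by
#' `variant`:
#'
#' * `catalytic-111`: M + AH2/AH- + O2 -> M + DHA + H2O2 with 1:1:1
#'   stoichiometry (the headline mechanism; third-order constants
#'   5.7e4/4.7e4 for Fe(III) and 7.7e4/2.8e6 for Cu(II), in M^-2 s^-1).
#' * `redox`: M(ox) + AH2/AH- -> M(red) + ascorbate radical; no H2O2 is
#'   produced in the metal step.
#' * `cu-halfO2`: the copper AH- reaction carries a half-order oxygen
#'   dependence, k [Cu(II)][AH-][O2]^1/2 (2.5-order constant 1.2e5).
#' * `cu-chloride-law`: k [Cu(II)][AH2+AH-]^1/2 [O2]^1/2, the rate law
#'   reported for high-chloride media.
#' * `catalytic+redox`: both families present; the redox copies get base
#'   ids `R14r`..`R17r` (used for mechanism-discrimination fits).
#'
#' Reversible rows are split into separate forward and backward reactions.
#' Rows tabulated with only an equilibrium constant are treated as fast
#' equilibria: the backward constant is `fast_kr` and the forward constant
#' `Keq * fast_kr`.  Lumped species (Fe(III)**, Cu(II)* etc.) expand into
#' one reaction instance per complex, sharing a single rate constant.
#'
#' @param variant Metal-ascorbate rate-law family (see above).
#' @param fast_kr Backward rate constant for Keq-only equilibria (1/s or
#'   divided by molarity per the dimensionality).  The default 1e3 keeps
#'   speciation equilibration at least five orders of magnitude faster than
#'   any competing chemistry while keeping cumulative equilibrium extents
#'   comparable to the concentrations they move, which keeps the flux
#'   ledger well conditioned.
#' @param catalytic_products `"dha"` (DHA + H2O2, the conclusion of the
#'   mechanism analysis) or `"radical"` (ascorbate radical + HO2.), the
#'   alternative product channel probed against hydroxyl-radical data.
#' @return An `aa_mechanism`.
#' @export
#' @examples
#' mech <- build_ascorbate_mechanism()
#' mech
#' get_rate_constant(mech, "R17")[1]   # 2.8e6
build_ascorbate_mechanism <- function(variant = c("catalytic-111", "redox",
                                              "cu-halfO2", "cu-chloride-law",
                                              "catalytic+redox"),
                                  fast_kr = 1e3,
                                  catalytic_products = c("dha", "radical")) {
  if (is.character(variant) && length(variant) == 1 &&
      !variant %in% c("catalytic-111", "redox", "cu-halfO2",
                      "cu-chloride-law", "catalytic+redox"))
    stop("unknown mechanism variant: '", variant,
         "' (use catalytic-111, redox, cu-halfO2, cu-chloride-law or catalytic+redox)")
  variant <- match.arg(variant)
  catalytic_products <- match.arg(catalytic_products)

  rl <- list()
  add <- function(x) {
    if (inherits(x, "aa_reaction")) x <- list(x)
    rl <<- c(rl, x)
  }

  ## -- ascorbate chemistry --
  add(.eqm("R1", "AH2 -> AH- + H+",  Keq = 7.94e-5, default_kr = fast_kr))
  add(.eqm("R2", "AH- -> A2- + H+",  Keq = 1.58e-12, default_kr = fast_kr))
  add(.eqm("R3", "AH. -> A.- + H+",  Keq = 7.24, default_kr = fast_kr))
  add(.rx("R4", "AH2 + OH. -> A.- + H2O + H+", 7.9e9, tags = "ros"))
  add(.rx("R5", "AH2 + HO2. -> A.- + H2O2 + H+", 1.6e4, tags = "ros"))
  # only the combination (0.200 k6 + k8) = 1.22e7 is constrained and the
  # 0.200 weighting is pH independent, so the k6/k8 split cannot affect the
  # dynamics; all of it is carried on R8.
  add(.rx("R6", "AH2 + O2.- -> A.- + H2O2", 0, tags = "ros",
          note = "k6 indistinguishable from k8; constrained sum carried on R8"))
  add(.rx("R7", "AH- + OH. -> A.- + H2O", 1.1e10, tags = "ros"))
  add(.rx("R8", "AH- + HO2. -> A.- + H2O2", 1.22e7, tags = "ros",
          note = "0.200 k6 + k8 = 1.22e7"))
  add(.rx("R9", "AH- + O2.- -> A.- + HO2-", 5e4, tags = "ros"))
  add(.rx("R10", "A.- + HO2. -> DHA + HO2-", 5e9))
  add(.rx("R11", "A.- + O2.- -> DHA + HO2-", 2.6e8, minus_h = 1))
  add(.eqm("R12", "2 A.- -> AH- + DHA", kf = 7e4, kr = 4.2e-12, Keq = 1.67e16,
           minus_h = 1))
  add(.eqm("R13", "2 A.- -> AH2 + DHA", kf = 8e7, kr = 3.8e-13, Keq = 2.1e20,
           minus_h = 2))

  ## -- metal-ascorbate step (variant dependent) --
  cat_prod_ah2 <- if (catalytic_products == "dha") "{M} + DHA + H2O2"
                  else "{M} + A.- + HO2. + H+"
  cat_prod_ahm <- if (catalytic_products == "dha") "{M} + DHA + H2O2"
                  else "{M} + A.- + HO2."
  cat_minus_ah2 <- 0
  cat_minus_ahm <- if (catalytic_products == "dha") 1 else 0
  add_catalytic <- function() {
    add(.lump("R14", .fe3_star_star(), paste("{M} + AH2 + O2 ->", cat_prod_ah2),
              5.7e4, release = FALSE, minus_h = cat_minus_ah2, tags = "catalytic"))
    add(.lump("R15", .fe3_star_star(), paste("{M} + AH- + O2 ->", cat_prod_ahm),
              4.7e4, release = FALSE, minus_h = cat_minus_ahm, tags = "catalytic"))
    add(.lump("R16", .cu2_star(), paste("{M} + AH2 + O2 ->", cat_prod_ah2),
              7.7e4, release = FALSE, minus_h = cat_minus_ah2, tags = "catalytic"))
    add(.lump("R17", .cu2_star(), paste("{M} + AH- + O2 ->", cat_prod_ahm),
              2.8e6, release = FALSE, minus_h = cat_minus_ahm, tags = "catalytic"))
  }
  add_redox <- function(suffix = "") {
    add(.lump(paste0("R14", suffix), .fe3_star_star(),
              "{M} + AH2 -> Fe2+ + A.- + 2 H+", 66, tags = "redox"))
    add(.lump(paste0("R15", suffix), .fe3_star_star(),
              "{M} + AH- -> Fe2+ + A.- + H+", 10, tags = "redox"))
    add(.lump(paste0("R16", suffix), .cu2_star(),
              "{M} + AH2 -> Cu+ + A.- + 2 H+", 880, tags = "redox"))
    add(.lump(paste0("R17", suffix), .cu2_star(),
              "{M} + AH- -> Cu+ + A.- + H+", 880, tags = "redox"))
  }
  if (variant == "catalytic-111") {
    add_catalytic()
  } else if (variant == "redox") {
    add_redox()
  } else if (variant == "catalytic+redox") {
    add_catalytic()
    add_redox("r")
  } else if (variant == "cu-halfO2") {
    add(.lump("R14", .fe3_star_star(), paste("{M} + AH2 + O2 ->", cat_prod_ah2),
              5.7e4, release = FALSE, tags = "catalytic"))
    add(.lump("R15", .fe3_star_star(), paste("{M} + AH- + O2 ->", cat_prod_ahm),
              4.7e4, release = FALSE, minus_h = cat_minus_ahm, tags = "catalytic"))
    add(.lump("R16", .cu2_star(), paste("{M} + AH2 + O2 ->", cat_prod_ah2),
              7.7e4, release = FALSE, tags = "catalytic"))
    # 2.5-order empirical law: k [Cu(II)][AH-][O2]^1/2
    for (m in .cu2_star()) {
      add(.rx(paste0("R17_", m),
              paste0(m, " + AH- + 0.5 O2 -> ", m, " + DHA + 0.5 H2O2"),
              1.2e5, base_id = "R17", tags = "catalytic",
              note = "empirical 1:1:0.5 rate law"))
    }
  } else if (variant == "cu-chloride-law") {
    add(.lump("R14", .fe3_star_star(), paste("{M} + AH2 + O2 ->", cat_prod_ah2),
              5.7e4, release = FALSE, tags = "catalytic"))
    add(.lump("R15", .fe3_star_star(), paste("{M} + AH- + O2 ->", cat_prod_ahm),
              4.7e4, release = FALSE, minus_h = cat_minus_ahm, tags = "catalytic"))
    # k [Cu(II)][AH2+AH-]^1/2 [O2]^1/2, consumption split pro rata between
    # AH2 and AH-: each branch carries order 1 on its own species and the
    # pooled total to the power -1/2.
    for (m in .cu2_star()) {
      add(.rx(paste0("R16a_", m),
              paste0(m, " + AH2 + 0.5 O2 -> ", m, " + DHA + 0.5 H2O2"),
              63, base_id = "R16", pool = c("AH2", "AH-"), pool_exp = -0.5,
              tags = "catalytic", note = "chloride-media 1:0.5:0.5 law"))
      add(.rx(paste0("R16b_", m),
              paste0(m, " + AH- + 0.5 O2 -> ", m, " + DHA + 0.5 H2O2"),
              63, base_id = "R16", pool = c("AH2", "AH-"), pool_exp = -0.5,
              tags = "catalytic", note = "chloride-media 1:0.5:0.5 law"))
    }
  }

  ## -- DHA measurement and degradation --
  add(.rx("R18", "oPDA + DHA -> DHAoPDA", 4.6, tags = "probe"))
  add(.rx("R19", "DHA + OH. -> product", 1e10, tags = "degradation"))
  add(.rx("R20", "DHA + H2O -> DKG", 5.8e-4, kspec = "R20", tags = "degradation",
          note = "hydrolysis; 5.8e-4 1/s at neutral pH, negligible at low pH"))
  add(.rx("R21", "DKG + OH. -> product", 1e10, tags = "degradation"))
  add(.rx("R22", "DHA + H2O2 -> product", 4.2e-2, tags = "degradation"))

  ## -- ROS reactions --
  add(.rx("R23", "2 OH. -> H2O2", 5.5e9))
  add(.rx("R24", "H2O2 + OH. -> HO2. + H2O", 3.2e7))
  add(.rx("R25", "O2.- + OH. -> OH- + O2", 1.01e10))
  add(.rx("R26", "HO2. + OH. -> H2O + O2", 7.1e9))
  add(.rx("R27", "O2.- + H2O2 -> OH- + OH. + O2", 0.13))
  add(.rx("R28", "2 O2.- -> O2 + H2O2", 6.0e5, minus_h = 2))
  add(.rx("R29", "HO2. + O2.- -> HO2- + O2", 9.7e7))
  add(.rx("R30", "H2O2 + HO2. -> H2O + O2 + OH.", 0.5))
  add(.rx("R31", "2 HO2. -> O2 + H2O2", 8.3e5))
  add(.rx("R32", "O22- + H+ -> HO2-", 1e10))
  add(.rx("R33", "HSO4- + OH. -> SO4.- + H2O", 3.5e5))

  ## -- general equilibria --
  add(.eqm("R34", "H2O -> H+ + OH-", kf = 1.3e-3, kr = 1.3e11, Keq = 1e-14))
  add(.eqm("R35", "H2O2 -> H+ + HO2-", kf = 1.26e-2, kr = 1e10, Keq = 1.26e-12))
  add(.eqm("R36", "HO2. -> H+ + O2.-", kf = 1.14e6, kr = 7.2e10, Keq = 1.58e-5))
  add(.eqm("R37", "H+ + SO42- -> HSO4-", Keq = 9.77e1, default_kr = fast_kr))

  ## -- inorganic iron --
  add(.eqm("R38", "Fe3+ + H2O -> FeOH2+ + H+", Keq = 6.11e-3, default_kr = fast_kr))
  add(.eqm("R39", "FeOH2+ + H2O -> Fe(OH)2+ + H+", Keq = 7.78e-6, default_kr = fast_kr))
  add(.eqm("R40", "Fe2+ + H2O -> FeOH+ + H+", Keq = 3.16e-10, default_kr = fast_kr))
  add(.eqm("R41", "Fe3+ + SO42- -> FeSO4+", Keq = 8.32e3, default_kr = fast_kr))
  add(.eqm("R42", "Fe3+ + 2 SO42- -> Fe(SO4)2-", Keq = 2.63e5, default_kr = fast_kr))
  add(.eqm("R43", "Fe2+ + SO42- -> FeSO4", Keq = 1.78e2, default_kr = fast_kr))
  add(.eqm("R44", "Cl- + Fe3+ -> FeCl2+", kf = 3e3, kr = 2.16e3, Keq = 1.39))
  add(.rx("R45", "Fe2+ + O2 -> Fe3+ + O2.-", 1e-4, kspec = "R45",
          note = "pH and temperature dependent; see k_fe2_o2()"))
  add(.lump("R46", .fe3_star(), "{M} + O2.- -> Fe2+ + O2", 5e7))
  add(.rx("R47", "FeSO4+ + O2.- -> Fe2+ + SO42- + O2", 1e3, note = "upper limit"))
  add(.rx("R48", "Fe(SO4)2- + O2.- -> Fe2+ + 2 SO42- + O2", 1e3, note = "upper limit"))
  add(.lump("R49", .fe3_star(), "{M} + HO2. -> Fe2+ + O2 + H+", 2e4))
  add(.rx("R50", "FeSO4+ + HO2. -> Fe2+ + SO42- + O2 + H+", 1e3, note = "upper limit"))
  add(.rx("R51", "Fe(SO4)2- + HO2. -> Fe2+ + 2 SO42- + O2 + H+", 1e3, note = "upper limit"))
  add(.eqm("R52", "Fe3+ + H2O2 -> Fe(HO2)2+ + H+", kf = 3.1e7, kr = 1e10, Keq = 3.1e-3))
  add(.eqm("R53", "FeOH2+ + H2O2 -> Fe(OH)(HO2)+ + H+", kf = 2e6, kr = 1e10, Keq = 2e-4))
  add(.lump("R54", .fe2_star(), "{M} + OH. -> Fe3+ + OH-", 2.7e8))
  add(.rx("R55", "FeSO4 + OH. -> Fe3+ + SO42- + OH-", 2.7e8))
  add(.lump("R56", .fe2_star(), "{M} + O2.- -> Fe3+ + O22-", 1e7))
  add(.rx("R57", "FeSO4 + O2.- -> Fe3+ + SO42- + O22-", 5e8))
  add(.lump("R58", .fe2_star(), "{M} + HO2. -> Fe3+ + HO2-", 1.2e6))
  add(.rx("R59", "FeSO4 + HO2. -> Fe3+ + SO42- + HO2-", 1.2e6))
  add(.rx("R60", "Fe2+ + H2O2 -> Fe3+ + OH. + OH-", 55, tags = "fenton"))
  add(.rx("R61", "FeOH+ + H2O2 -> Fe3+ + OH. + 2 OH-", 55, tags = "fenton",
          note = "same as R60"))
  add(.rx("R62", "FeSO4 + H2O2 -> Fe3+ + SO42- + OH. + OH-", 78, tags = "fenton"))
  add(.rx("R63", "Fe(HO2)2+ -> HO2. + Fe2+", 2.3e-3))
  add(.rx("R64", "Fe(OH)(HO2)+ -> Fe2+ + HO2. + OH-", 2.3e-3))

  ## -- copper --
  add(.eqm("R65", "Cu2+ + H2O -> CuOH+ + H+", Keq = 1.12e-8, default_kr = fast_kr))
  add(.eqm("R66", "Cu2+ + 2 H2O -> Cu(OH)2 + 2 H+", Keq = 6.31e-17, default_kr = fast_kr))
  add(.eqm("R67", "Cu2+ + 3 H2O -> Cu(OH)3- + 3 H+", Keq = 2.51e-27, default_kr = fast_kr))
  add(.eqm("R68", "Cu2+ + 4 H2O -> Cu(OH)42- + 4 H+", Keq = 1.82e-40, default_kr = fast_kr))
  add(.eqm("R69", "2 Cu2+ + H2O -> Cu2OH3+ + H+", Keq = 3.98e-7, default_kr = fast_kr))
  add(.eqm("R70", "2 Cu2+ + 2 H2O -> Cu2(OH)22+ + 2 H+", Keq = 3.72e-11, default_kr = fast_kr))
  add(.eqm("R71", "3 Cu2+ + 4 H2O -> Cu3(OH)42+ + 4 H+", Keq = 7.94e-22, default_kr = fast_kr))
  add(.eqm("R72", "Cu2+ + SO42- -> CuSO4", Keq = 223.9, default_kr = fast_kr))
  add(.eqm("R73", "Cu2+ + Cl- -> CuCl+", Keq = 6.76, default_kr = fast_kr))
  add(.eqm("R74", "Cu2+ + 2 Cl- -> CuCl2", Keq = 3.98, default_kr = fast_kr))
  # R75 prints all of kf, kr, Keq; the forward reaction is instantiated for
  # every Cu(II)* complex (releasing its ligand) while the single backward
  # reaction regenerates the free ion.
  add(.lump("R75f", .cu2_star(), "{M} + OH. -> CuOH2+", 3.5e8,
            tags = "equilibrium-forward", base_id = "R75"))
  add(.rx("R75b", "CuOH2+ -> Cu2+ + OH.", 3e4, base_id = "R75",
          tags = "equilibrium-backward"))
  add(.lump("R76", .cu2_star(), "{M} + HO2. -> Cu+ + O2 + H+", 1e8))
  add(.lump("R77", .cu2_star(), "{M} + H2O2 -> Cu+ + O2.- + 2 H+", NA,
            note = "upper limit for Cu2+/CuOH+/CuSO4",
            k_by_member = list("Cu2+" = 1, "CuOH+" = 1, "CuSO4" = 1,
                               "CuCl+" = 70, "CuCl2" = 70)))
  add(.eqm("R78", "Cu+ + O2 -> Cu2+ + O2.-", kf = 4.6e5, kr = 8e9))
  add(.rx("R79", "Cu+ + OH. -> Cu2+ + OH-", 3e9))
  add(.rx("R80", "Cu+ + H2O2 -> Cu2+ + OH. + OH-", 100, note = "upper limit"))
  add(.rx("R81", "Cu+ + H2O2 -> Cu3+ + 2 OH-", 61))
  add(.rx("R82", "Cu+ + Cu3+ -> 2 Cu2+", 3.5e9))
  add(.rx("R83", "Cu+ + HO2. -> Cu2+ + H2O2", 2.3e9, minus_h = 1))
  add(.rx("R84", "Cu+ + O2.- -> Cu2+ + H2O2", 9.4e9, minus_h = 2))

  ## -- buffers and the OH. probe --
  add(.eqm("R85", "HEPES -> H+ + HEPES-", Keq = 1e-3, default_kr = fast_kr))
  add(.eqm("R86", "HEPES- -> H+ + HEPES2-", Keq = 2.73e-8, default_kr = fast_kr))
  add(.eqm("R87", "BA -> H+ + BA-", Keq = 6.3e-5, default_kr = fast_kr))
  add(.rx("R88", "BA + OH. -> BAprod", 1.03e9, tags = "probe"))
  add(.rx("R89", "BA- + OH. -> BAprod", 4.66e9, tags = "probe"))
  add(.eqm("R90", "H3PO4 -> H+ + H2PO4-", Keq = 7.08e-3, default_kr = fast_kr))
  add(.eqm("R91", "H2PO4- -> H+ + HPO42-", Keq = 6.31e-8, default_kr = fast_kr))
  add(.eqm("R92", "HPO42- -> H+ + PO43-", Keq = 4.79e-13, default_kr = fast_kr))
  add(.rx("R93", "H2PO4- + OH. -> H2PO4. + OH-", 2e4))
  add(.rx("R94", "HPO42- + OH. -> HPO4.- + OH-", 1.5e5))
  add(.rx("R95", "PO43- + OH. -> PO4.2- + OH-", 7e6))

  .new_mechanism(aa_species_table(), rl, variant, fast_kr,
                 metadata = list(catalytic_products = catalytic_products))
}

# ---- condition-dependent rate constants -------------------------------------

#' Rate constant of Fe(II) oxidation by molecular oxygen
#'
#' The Fe2+ + O2 rate constant is strongly pH and temperature dependent:
#' ~1e-5 M^-1 s^-1 below pH 4 at room temperature (1e-4 at 37 C), 0.11 and
#' 0.17 M^-1 s^-1 at pH 6.0 and 6.5 (linear interpolation between), and
#' 0.39 M^-1 s^-1 at pH 7 (3.9 at 37 C).  Between the anchor pHs the
#' constant is interpolated log-linearly; the 37 C curve is the room
#' temperature curve scaled by 10 (a factor of 10 per 15 C).
#'
#' @param ph Solution pH.
#' @param temperature Temperature in Celsius; >= 30 selects the 37 C curve.
#' @return Rate constant in M^-1 s^-1.
#' @export
#' @examples
#' k_fe2_o2(2.8, 37)   # 1e-4
#' k_fe2_o2(6.3, 25)   # ~0.146
k_fe2_o2 <- function(ph, temperature = 25) {
  stopifnot(is.finite(ph), ph >= 0, ph <= 14)
  room <- if (ph <= 4) {
    1e-5
  } else if (ph < 6) {
    10^(log10(1e-5) + (ph - 4) / 2 * (log10(0.11) - log10(1e-5)))
  } else if (ph <= 6.5) {
    0.11 + (ph - 6) / 0.5 * (0.17 - 0.11)
  } else if (ph < 7) {
    10^(log10(0.17) + (ph - 6.5) / 0.5 * (log10(0.39) - log10(0.17)))
  } else {
    0.39
  }
  if (temperature >= 30) 10 * room else room
}

# DHA hydrolysis pH factor: 0 below pH 4, 1 above pH 6, linear between.
.k20_ph_factor <- function(ph) {
  if (ph <= 4) 0 else if (ph >= 6) 1 else (ph - 4) / 2
}

#' Resolve condition-dependent rate constants
#'
#' Returns the vector of effective rate constants for a mechanism at given
#' pH and temperature: the Fe(II) + O2 constant follows [k_fe2_o2()] and
#' DHA hydrolysis is scaled by a pH ramp (zero at pH <= 4, full speed at
#' pH >= 6).
#'
#' @param mech An `aa_mechanism`.
#' @param ph,temperature Segment conditions.
#' @return Named numeric vector of rate constants (by reaction id).
#' @export
resolve_rate_constants <- function(mech, ph, temperature = 25) {
  k <- vapply(mech$reactions, `[[`, numeric(1), "k")
  names(k) <- reaction_ids(mech)
  spec <- vapply(mech$reactions, `[[`, character(1), "kspec")
  k[spec == "R45"] <- k_fe2_o2(ph, temperature)
  k[spec == "R20"] <- 5.8e-4 * .k20_ph_factor(ph)
  k
}

# ---- validation -------------------------------------------------------------

#' Validate a mechanism
#'
#' Report-only checks: per-reaction conserved-moiety balance (iron, copper,
#' ascorbate, sulfate, chloride, phosphorus, probe), consistency of tabulated
#' kf/kr pairs with their tabulated equilibrium constants (1% relative), and
#' undeclared species.  The full mechanism built by
#' [build_ascorbate_mechanism()] passes with zero errors.
#'
#' @param mech An `aa_mechanism`.
#' @param keq_tol Relative tolerance for the kf/kr vs Keq check.
#' @return A list of class `aa_validation` with elements `errors` (character
#'   vector), `moiety` (per-reaction imbalance matrix) and `n_reactions`.
#' @export
validate_mechanism <- function(mech, keq_tol = 0.01) {
  errors <- character(0)
  moieties <- aa_moiety_names()
  counts <- as.matrix(mech$species[, moieties])
  rownames(counts) <- mech$species$name
  imb <- matrix(0, length(mech$reactions), length(moieties),
                dimnames = list(reaction_ids(mech), moieties))
  for (i in seq_along(mech$reactions)) {
    r <- mech$reactions[[i]]
    unknown <- setdiff(c(names(r$reactants), names(r$products)), mech$species$name)
    if (length(unknown)) {
      errors <- c(errors, paste0(r$id, ": undeclared species ",
                                 paste(unknown, collapse = ", ")))
      next
    }
    lhs <- colSums(counts[names(r$reactants), , drop = FALSE] * r$reactants)
    rhs <- colSums(counts[names(r$products), , drop = FALSE] * r$products)
    imb[i, ] <- rhs - lhs
    bad <- moieties[abs(rhs - lhs) > 1e-12]
    if (length(bad))
      errors <- c(errors, paste0(r$id, ": moiety imbalance in ",
                                 paste(bad, collapse = ", ")))
    if (is.na(r$k) || r$k < 0)
      errors <- c(errors, paste0(r$id, ": invalid rate constant"))
  }
  # tabulated kf/kr/Keq triples must be mutually consistent to 1%
  triples <- list(R12 = 1.67e16, R13 = 2.1e20, R34 = 1e-14, R35 = 1.26e-12,
                  R36 = 1.58e-5, R44 = 1.39, R52 = 3.1e-3, R53 = 2e-4,
                  R75 = 1.17e4)
  ids <- reaction_ids(mech, base = TRUE)
  for (nm in names(triples)) {
    fwd <- which(ids == nm & vapply(mech$reactions, function(r)
      "equilibrium-forward" %in% r$tags, logical(1)))
    bwd <- which(ids == nm & vapply(mech$reactions, function(r)
      "equilibrium-backward" %in% r$tags, logical(1)))
    if (!length(fwd) || !length(bwd)) next
    kf <- mech$reactions[[fwd[1]]]$k
    kr <- mech$reactions[[bwd[1]]]$k
    rel <- abs(kf / kr - triples[[nm]]) / triples[[nm]]
    if (rel > keq_tol)
      errors <- c(errors, sprintf("%s: kf/kr = %.4g vs tabulated Keq %.4g (%.2f%%)",
                                  nm, kf / kr, triples[[nm]], 100 * rel))
  }
  structure(list(errors = errors, moiety = imb,
                 n_reactions = length(mech$reactions)),
            class = "aa_validation")
}

#' @export
print.aa_validation <- function(x, ...) {
  cat(sprintf("mechanism validation: %d reactions, %d error(s)\n",
              x$n_reactions, length(x$errors)))
  if (length(x$errors)) cat(paste0("  - ", x$errors, collapse = "\n"), "\n")
  invisible(x)
}
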