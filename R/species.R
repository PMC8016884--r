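#' Species table for the ascorbate oxidation mechanism
#'
#' Returns the full set of chemical species used by
#' [build_ascorbate_mechanism()], one row per species, with default initial
#' concentrations (mol/L) and conserved-moiety group counts.  The moiety
#' columns (`iron`, `copper`, `ascorbate`, `sulfate`, `chloride`,
#' `phosphorus`, `probe`) give how many units of each conserved moiety the
#' species carries; they drive the per-reaction balance checks in
#' [validate_mechanism()] and the trajectory drift checks in
#' [conservation_report()].
#'
#' Sink species (`product`, `DKG`, `DHAoPDA`) carry the ascorbate moiety so
#' that the ascorbate budget closes even after degradation and
#' derivatization.  `BAprod` carries the benzoate probe moiety.  Water is a
#' constant-activity species (never integrated, zero kinetic order).
#'
#' @return A data.frame with columns `name`, `default_initial` and one
#'   numeric column per moiety group.
#' @export
#' @examples
#' sp <- aa_species_table()
#' sp[sp$iron > 0, "name"]
aa_species_table <- function() {
  # name, init, iron, copper, ascorbate, sulfate, chloride, phosphorus, probe
  def <- list(
    # ascorbate family
    list("AH2",          0, 0, 0, 1, 0, 0, 0, 0),
    list("AH-",          0, 0, 0, 1, 0, 0, 0, 0),
    list("A2-",          0, 0, 0, 1, 0, 0, 0, 0),
    list("AH.",          0, 0, 0, 1, 0, 0, 0, 0),
    list("A.-",          0, 0, 0, 1, 0, 0, 0, 0),
    list("DHA",          0, 0, 0, 1, 0, 0, 0, 0),
    list("DKG",          0, 0, 0, 1, 0, 0, 0, 0),
    list("DHAoPDA",      0, 0, 0, 1, 0, 0, 0, 0),
    list("product",      0, 0, 0, 1, 0, 0, 0, 0),
    list("oPDA",         0, 0, 0, 0, 0, 0, 0, 0),
    # ROS / water
    list("OH.",          0, 0, 0, 0, 0, 0, 0, 0),
    list("HO2.",         0, 0, 0, 0, 0, 0, 0, 0),
    list("O2.-",         0, 0, 0, 0, 0, 0, 0, 0),
    list("H2O2",         0, 0, 0, 0, 0, 0, 0, 0),
    list("HO2-",         0, 0, 0, 0, 0, 0, 0, 0),
    list("O2",           0, 0, 0, 0, 0, 0, 0, 0),
    list("O22-",         0, 0, 0, 0, 0, 0, 0, 0),
    list("H2O",          1, 0, 0, 0, 0, 0, 0, 0),
    list("H+",           0, 0, 0, 0, 0, 0, 0, 0),
    list("OH-",          0, 0, 0, 0, 0, 0, 0, 0),
    # sulfate / chloride
    list("SO42-",        0, 0, 0, 0, 1, 0, 0, 0),
    list("HSO4-",        0, 0, 0, 0, 1, 0, 0, 0),
    list("SO4.-",        0, 0, 0, 0, 1, 0, 0, 0),
    list("Cl-",          0, 0, 0, 0, 0, 1, 0, 0),
    # iron(II)
    list("Fe2+",         0, 1, 0, 0, 0, 0, 0, 0),
    list("FeOH+",        0, 1, 0, 0, 0, 0, 0, 0),
    list("FeSO4",        0, 1, 0, 0, 1, 0, 0, 0),
    # iron(III)
    list("Fe3+",         0, 1, 0, 0, 0, 0, 0, 0),
    list("FeOH2+",       0, 1, 0, 0, 0, 0, 0, 0),
    list("Fe(OH)2+",     0, 1, 0, 0, 0, 0, 0, 0),
    list("FeCl2+",       0, 1, 0, 0, 0, 1, 0, 0),
    list("FeSO4+",       0, 1, 0, 0, 1, 0, 0, 0),
    list("Fe(SO4)2-",    0, 1, 0, 0, 2, 0, 0, 0),
    list("Fe(HO2)2+",    0, 1, 0, 0, 0, 0, 0, 0),
    list("Fe(OH)(HO2)+", 0, 1, 0, 0, 0, 0, 0, 0),
    # copper
    list("Cu2+",         0, 0, 1, 0, 0, 0, 0, 0),
    list("CuOH+",        0, 0, 1, 0, 0, 0, 0, 0),
    list("Cu(OH)2",      0, 0, 1, 0, 0, 0, 0, 0),
    list("Cu(OH)3-",     0, 0, 1, 0, 0, 0, 0, 0),
    list("Cu(OH)42-",    0, 0, 1, 0, 0, 0, 0, 0),
    list("Cu2OH3+",      0, 0, 2, 0, 0, 0, 0, 0),
    list("Cu2(OH)22+",   0, 0, 2, 0, 0, 0, 0, 0),
    list("Cu3(OH)42+",   0, 0, 3, 0, 0, 0, 0, 0),
    list("CuSO4",        0, 0, 1, 0, 1, 0, 0, 0),
    list("CuCl+",        0, 0, 1, 0, 0, 1, 0, 0),
    list("CuCl2",        0, 0, 1, 0, 0, 2, 0, 0),
    list("CuOH2+",       0, 0, 1, 0, 0, 0, 0, 0),
    list("Cu+",          0, 0, 1, 0, 0, 0, 0, 0),
    list("Cu3+",         0, 0, 1, 0, 0, 0, 0, 0),
    # buffers and the hydroxyl-radical probe
    list("HEPES",        0, 0, 0, 0, 0, 0, 0, 0),
    list("HEPES-",       0, 0, 0, 0, 0, 0, 0, 0),
    list("HEPES2-",      0, 0, 0, 0, 0, 0, 0, 0),
    list("BA",           0, 0, 0, 0, 0, 0, 0, 1),
    list("BA-",          0, 0, 0, 0, 0, 0, 0, 1),
    list("BAprod",       0, 0, 0, 0, 0, 0, 0, 1),
    list("H3PO4",        0, 0, 0, 0, 0, 0, 1, 0),
    list("H2PO4-",       0, 0, 0, 0, 0, 0, 1, 0),
    list("HPO42-",       0, 0, 0, 0, 0, 0, 1, 0),
    list("PO43-",        0, 0, 0, 0, 0, 0, 1, 0),
    list("H2PO4.",       0, 0, 0, 0, 0, 0, 1, 0),
    list("HPO4.-",       0, 0, 0, 0, 0, 0, 1, 0),
    list("PO4.2-",       0, 0, 0, 0, 0, 0, 1, 0)
  )
  out <- data.frame(
    name            = vapply(def, function(x) x[[1]], character(1)),
    default_initial = vapply(def, function(x) as.numeric(x[[2]]), numeric(1)),
    iron            = vapply(def, function(x) as.numeric(x[[3]]), numeric(1)),
    copper          = vapply(def, function(x) as.numeric(x[[4]]), numeric(1)),
    ascorbate       = vapply(def, function(x) as.numeric(x[[5]]), numeric(1)),
    sulfate         = vapply(def, function(x) as.numeric(x[[6]]), numeric(1)),
    chloride        = vapply(def, function(x) as.numeric(x[[7]]), numeric(1)),
    phosphorus      = vapply(def, function(x) as.numeric(x[[8]]), numeric(1)),
    probe           = vapply(def, function(x) as.numeric(x[[9]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Names of the conserved-moiety groups
#' @return Character vector of moiety column names in [aa_species_table()].
#' @keywords internal
aa_moiety_names <- function() {
  c("iron", "copper", "ascorbate", "sulfate", "chloride", "phosphorus", "probe")
}

# species that are held fixed (never integrated)
.constant_species <- function(ph_mode = c("clamped", "dynamic")) {
  ph_mode <- match.arg(ph_mode)
  if (ph_mode == "clamped") c("H2O", "H+", "OH-") else "H2O"
}

# lumped metal groups (table footnotes): each lump shares one rate constant
.fe3_star_star <- function() c("Fe3+", "FeOH2+", "Fe(OH)2+", "FeCl2+", "FeSO4+", "Fe(SO4)2-")
.fe3_star      <- function() c("Fe3+", "FeOH2+", "Fe(OH)2+", "FeCl2+")
.fe2_star      <- function() c("Fe2+", "FeOH+")
.cu2_star      <- function() c("Cu2+", "CuOH+", "CuSO4", "CuCl+", "CuCl2")

# ligands released when a lumped complex is transformed (moiety balance)
.released_ligands <- function(metal_species) {
  switch(metal_species,
    "Fe3+"          = c(),
    "FeOH2+"        = c("OH-" = 1),
    "Fe(OH)2+"      = c("OH-" = 2),
    "FeCl2+"        = c("Cl-" = 1),
    "FeSO4+"        = c("SO42-" = 1),
    "Fe(SO4)2-"     = c("SO42-" = 2),
    "Fe2+"          = c(),
    "FeOH+"         = c("OH-" = 1),
    "FeSO4"         = c("SO42-" = 1),
    "Cu2+"          = c(),
    "CuOH+"         = c("OH-" = 1),
    "CuSO4"         = c("SO42-" = 1),
    "CuCl+"         = c("Cl-" = 1),
    "CuCl2"         = c("Cl-" = 2),
    stop("no ligand table for species ", metal_species)
  )
}
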