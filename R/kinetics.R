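# Stiff integration of a mechanism over one well-mixed, isothermal,
# closed-reactor segment, with per-reaction cumulative-extent accounting.

#' Air-saturated dissolved oxygen concentration
#'
#' Henry's-law dissolved O2 for air-saturated water: 2.58e-4 M at 25 C and
#' 2.10e-4 M at 37 C, interpolated linearly in temperature.
#'
#' @param temperature Celsius.
#' @return mol/L.
#' @export
o2_saturation <- function(temperature = 25) {
  2.58e-4 + (temperature - 25) * (2.10e-4 - 2.58e-4) / 12
}

#' Conditions for one reactor segment
#'
#' @param ph Solution pH (used for clamped [H+]/[OH-] and the
#'   condition-dependent rate constants).
#' @param temperature Celsius.
#' @param duration Seconds (>= 0).
#' @param initial Named concentrations (mol/L) overriding the species
#'   defaults (which are zero).
#' @param o2 Initial dissolved O2 (mol/L); default air saturation at
#'   `temperature`.  The reactor is closed: no replenishment.
#' @param ph_mode `"clamped"` (fixed [H+], [OH-]; the buffered default) or
#'   `"dynamic"` (protons integrated explicitly).
#' @return An object of class `aa_conditions`.
#' @export
segment_conditions <- function(ph = 2.8, temperature = 25, duration = 1200,
                               initial = c(), o2 = NULL,
                               ph_mode = c("clamped", "dynamic")) {
  ph_mode <- match.arg(ph_mode)
  stopifnot(duration >= 0, ph >= 0, ph <= 14, all(initial >= 0))
  if (is.null(o2)) o2 <- o2_saturation(temperature)
  structure(list(ph = ph, temperature = temperature, duration = duration,
                 initial = initial, o2 = o2, ph_mode = ph_mode),
            class = "aa_conditions")
}

# initial concentration vector for a mechanism under given conditions
.initial_state <- function(mech, cond) {
  c0 <- setNames(mech$species$default_initial, mech$species$name)
  bad <- setdiff(names(cond$initial), names(c0))
  if (length(bad)) stop("unknown species in initial: ", paste(bad, collapse = ", "))
  c0[names(cond$initial)] <- cond$initial
  if ("O2" %in% names(c0)) c0["O2"] <- cond$o2
  if ("H+" %in% names(c0)) c0["H+"] <- 10^(-cond$ph)
  if ("OH-" %in% names(c0)) c0["OH-"] <- 1e-14 / 10^(-cond$ph)
  c0
}

# flatten a mechanism + conditions into the arrays the compiled core reads
.compile_mechanism <- function(mech, cond, mode) {
  sp <- mech$species$name
  idx <- setNames(seq_along(sp) - 1L, sp)
  n_rx <- length(mech$reactions)
  k <- resolve_rate_constants(mech, cond$ph, cond$temperature)

  rt_ptr <- integer(n_rx + 1); rt_sp <- integer(0); rt_ord <- numeric(0)
  pl_ptr <- integer(n_rx + 1); pl_sp <- integer(0); pool_exp <- numeric(n_rx)
  st_ptr <- integer(n_rx + 1); st_sp <- integer(0); st_nu <- numeric(0)
  for (j in seq_len(n_rx)) {
    r <- mech$reactions[[j]]
    o <- r$orders
    rt_sp <- c(rt_sp, idx[names(o)]); rt_ord <- c(rt_ord, unname(o))
    rt_ptr[j + 1] <- length(rt_sp)
    if (!is.null(r$pool)) {
      pl_sp <- c(pl_sp, idx[r$pool])
      pool_exp[j] <- r$pool_exp
    }
    pl_ptr[j + 1] <- length(pl_sp)
    net <- r$products
    for (s in names(r$reactants)) {
      net[s] <- (if (s %in% names(net)) net[[s]] else 0) - r$reactants[[s]]
    }
    net <- net[net != 0]
    st_sp <- c(st_sp, idx[names(net)]); st_nu <- c(st_nu, unname(net))
    st_ptr[j + 1] <- length(st_sp)
  }
  clamp_sp <- .constant_species(cond$ph_mode)
  clamp <- as.integer(sp %in% clamp_sp)
  c0 <- .initial_state(mech, cond)
  list(n_sp = length(sp), mode = as.integer(mode), k = unname(k),
       c0 = unname(c0), clamp = clamp,
       rt_ptr = rt_ptr, rt_sp = as.integer(rt_sp), rt_ord = rt_ord,
       pl_ptr = pl_ptr, pl_sp = as.integer(pl_sp), pool_exp = pool_exp,
       st_ptr = st_ptr, st_sp = as.integer(st_sp), st_nu = st_nu,
       species = sp, k_named = k, c0_named = c0)
}

#' Assemble the mass-action right-hand side of a mechanism
#'
#' Returns a pure-R rate function `d[X]/dt = sum_j nu_j k_j prod [S]^o` for
#' the given mechanism and conditions, together with the per-reaction rate
#' evaluator.  Under clamped pH, [H+] and [OH-] are held fixed (their
#' derivatives are zero).  This R implementation is independent of the
#' compiled core used by [integrate_segment()] and serves as its
#' cross-check.  Species that appear in no reaction are retained as
#' constants (with a warning).
#'
#' @param mech An `aa_mechanism`.
#' @param cond An `aa_conditions` (only `ph`, `temperature`, `ph_mode`
#'   matter here).
#' @param warn Warn about species outside every reaction.
#' @return List with `rhs(t, conc)` (named derivative vector), `rates(conc)`
#'   (per-reaction rates), `species`, and the initial state `c0`.
#' @export
assemble_rhs <- function(mech, cond = segment_conditions(), warn = FALSE) {
  cm <- .compile_mechanism(mech, cond, mode = 0L)
  sp <- cm$species
  n_rx <- length(cm$k)
  reacting <- unique(sp[c(cm$rt_sp, cm$st_sp, cm$pl_sp) + 1L])
  idle <- setdiff(sp, c(reacting, .constant_species(cond$ph_mode)))
  if (warn && length(idle))
    warning("species with no reactions retained as constant: ",
            paste(idle, collapse = ", "))
  rx <- mech$reactions
  clamp <- cm$clamp == 1L
  # dense order matrix (reaction x species) and net stoichiometry matrix;
  # rates evaluated in log space (clipped at zero concentration)
  ord <- matrix(0, n_rx, length(sp), dimnames = list(NULL, sp))
  for (j in seq_len(n_rx)) {
    o <- rx[[j]]$orders
    if (length(o)) ord[j, names(o)] <- o
  }
  nmat <- .extent_matrix(mech, sp)      # species x reaction
  pools <- which(vapply(rx, function(r) !is.null(r$pool), logical(1)))
  rates_fun <- function(conc) {
    logc <- pmax(log(pmax(conc, 0)), -700)
    r <- cm$k * drop(exp(ord %*% logc))
    for (j in pools) {
      s <- sum(pmax(conc[rx[[j]]$pool], 0))
      r[j] <- r[j] * if (s > 0) s^rx[[j]]$pool_exp else 0
    }
    r
  }
  rhs_fun <- function(t, conc) {
    d <- drop(nmat %*% rates_fun(conc))
    d[clamp] <- 0
    setNames(d, sp)
  }
  list(rhs = rhs_fun, rates = rates_fun, species = sp, c0 = cm$c0_named)
}

#' Integrate one reactor segment
#'
#' Stiffly integrates the mass-action ODEs of `mech` over a closed,
#' isothermal segment.  With `ledger = TRUE` the integration is carried out
#' in reaction-extent coordinates (`c = c0 + N e`), so the cumulative
#' per-reaction extents returned in the flux ledger satisfy the
#' stoichiometric bookkeeping identity exactly; with `ledger = FALSE` the
#' species concentrations are the state (faster; used in fitting loops).
#'
#' @param mech An `aa_mechanism`.
#' @param cond An `aa_conditions`.
#' @param ledger Keep per-reaction cumulative extents?
#' @param n_out Number of output time points (>= 2).
#' @param rtol,atol Relative/absolute integration tolerances (absolute in
#'   mol/L; the default resolves sub-nanomolar radicals against 1e-4 M
#'   reservoirs).
#' @param engine `"compiled"` (the C core with analytic Jacobian) or `"r"`
#'   (the independent R right-hand side via [deSolve::lsoda()], for
#'   cross-checks).
#' @param maxsteps Maximum internal integrator steps.
#' @return An `aa_segment_result`: `times`, concentration matrix `conc`
#'   (time x species, mol/L), extent matrix `extents` (time x reaction,
#'   mol/L; `NULL` unless `ledger`), the conditions, and the mechanism.
#' @export
integrate_segment <- function(mech, cond, ledger = TRUE, n_out = 25,
                              rtol = 1e-8, atol = 1e-16,
                              engine = c("compiled", "r"),
                              maxsteps = 200000) {
  engine <- match.arg(engine)
  stopifnot(inherits(mech, "aa_mechanism"), inherits(cond, "aa_conditions"))
  mode <- if (ledger) 1L else 0L
  cm <- .compile_mechanism(mech, cond, mode)
  sp <- cm$species
  n_rx <- length(cm$k)
  rid <- reaction_ids(mech)

  if (cond$duration == 0) {
    conc <- matrix(cm$c0_named, 1, length(sp), dimnames = list(NULL, sp))
    ext <- if (ledger) matrix(0, 1, n_rx, dimnames = list(NULL, rid)) else NULL
    return(structure(list(times = 0, conc = conc, extents = ext,
                          conditions = cond, mech = mech, engine = engine),
                     class = "aa_segment_result"))
  }

  times <- seq(0, cond$duration, length.out = max(2L, n_out))
  if (engine == "compiled") {
    .Call("C_mech_load", cm, PACKAGE = "ascorbox")
    y0 <- if (mode == 0L) unname(cm$c0) else numeric(n_rx)
    out <- deSolve::lsoda(y = y0, times = times, func = "mech_deriv",
                          parms = NULL, jacfunc = "mech_jac",
                          jactype = "fullusr", dllname = "ascorbox",
                          initfunc = NULL, rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
  } else {
    a <- assemble_rhs(mech, cond)
    fr <- function(t, y, p) list(unname(a$rhs(t, setNames(y, sp))))
    if (mode == 0L) {
      out <- deSolve::lsoda(y = unname(cm$c0), times = times, func = fr,
                            parms = NULL, rtol = rtol, atol = atol,
                            maxsteps = maxsteps)
    } else {
      # extent coordinates with the R rate function
      st <- .extent_matrix(mech, sp)
      clamp <- cm$clamp == 1L
      fe <- function(t, e, p) {
        conc <- cm$c0_named + drop(st %*% e)
        conc[clamp] <- cm$c0_named[clamp]
        list(unname(a$rates(conc)))
      }
      out <- deSolve::lsoda(y = numeric(n_rx), times = times, func = fe,
                            parms = NULL, rtol = rtol, atol = atol,
                            maxsteps = maxsteps)
    }
  }
  .check_integration(out, times, sp, mech)
  tt <- out[, 1]
  ystate <- out[, -1, drop = FALSE]
  if (mode == 0L) {
    conc <- ystate
    colnames(conc) <- sp
    ext <- NULL
  } else {
    ext <- ystate
    colnames(ext) <- rid
    st <- .extent_matrix(mech, sp)
    conc <- matrix(rep(cm$c0_named, each = nrow(ext)), nrow(ext), length(sp)) +
      ext %*% t(st)
    clamp <- cm$clamp == 1L
    conc[, clamp] <- matrix(rep(cm$c0_named[clamp], each = nrow(conc)),
                            nrow(conc))
    colnames(conc) <- sp
  }
  structure(list(times = tt, conc = conc, extents = ext, conditions = cond,
                 mech = mech, engine = engine),
            class = "aa_segment_result")
}

# species x reaction net-stoichiometry matrix (clamped rows NOT zeroed)
.extent_matrix <- function(mech, sp = mech$species$name) {
  n_rx <- length(mech$reactions)
  st <- matrix(0, length(sp), n_rx, dimnames = list(sp, reaction_ids(mech)))
  for (j in seq_len(n_rx)) {
    r <- mech$reactions[[j]]
    for (s in names(r$products)) st[s, j] <- st[s, j] + r$products[[s]]
    for (s in names(r$reactants)) st[s, j] <- st[s, j] - r$reactants[[s]]
  }
  st
}

.check_integration <- function(out, times, sp, mech) {
  istate <- attr(out, "istate")
  ok <- !is.null(istate) && istate[1] >= 0 && nrow(out) == length(times) &&
    !anyNA(out[nrow(out), ])
  if (!ok) {
    # diagnose: species with the largest derivative magnitude at the last
    # successful state
    last <- out[max(1, nrow(out)), -1]
    worst <- if (anyNA(last)) "unknown" else {
      d <- tryCatch(.Call("C_mech_eval", unname(last), PACKAGE = "ascorbox")$ydot,
                    error = function(e) NULL)
      if (is.null(d)) "unknown" else sp[which.max(abs(d[seq_along(sp)]))]
    }
    stop("stiff integration failed to converge (worst-behaved species: ",
         worst, ")")
  }
  invisible(TRUE)
}

#' @export
print.aa_segment_result <- function(x, ...) {
  cat(sprintf("<aa_segment_result> %.4g s, %d species%s\n",
              max(x$times), ncol(x$conc),
              if (is.null(x$extents)) "" else
                sprintf(", ledger over %d reactions", ncol(x$extents))))
  invisible(x)
}

#' Final concentrations of a segment
#' @param res An `aa_segment_result`.
#' @return Named vector (mol/L).
#' @export
final_state <- function(res) {
  setNames(res$conc[nrow(res$conc), ], colnames(res$conc))
}

# ---- flux accounting --------------------------------------------------------

# net consumption of `species_set` by each reaction (mol per unit extent)
.consumption_of <- function(mech, species_set) {
  st <- .extent_matrix(mech)
  cons <- -colSums(st[species_set, , drop = FALSE])
  pmax(cons, 0)
}

#' Catalytic-to-ROS pathway attribution ratio
#'
#' Partitions cumulative ascorbic acid (AH2 + AH-) consumption between the
#' direct metal-catalysed reactions (table rows R14-R17) and the reactive
#' oxygen species reactions (rows R4-R9: attack by OH., HO2. and O2.-), and
#' returns their ratio.  Requires a segment integrated with
#' `ledger = TRUE`.
#'
#' @param res An `aa_segment_result` with a flux ledger.
#' @return List with `ratio` (Inf if the ROS pathway consumed nothing),
#'   `catalytic` and `ros` (mol/L consumed).
#' @export
pathway_ratio <- function(res) {
  if (is.null(res$extents)) stop("segment was integrated without a flux ledger")
  mech <- res$mech
  base <- reaction_ids(mech, base = TRUE)
  ext <- res$extents[nrow(res$extents), ]
  cons <- .consumption_of(mech, c("AH2", "AH-"))
  cat_ids <- base %in% c("R14", "R15", "R16", "R17")
  ros_ids <- base %in% c("R4", "R5", "R6", "R7", "R8", "R9")
  catalytic <- sum(ext[cat_ids] * cons[cat_ids])
  ros <- sum(ext[ros_ids] * cons[ros_ids])
  list(ratio = if (ros > 0) catalytic / ros else Inf,
       catalytic = catalytic, ros = ros)
}

#' DHA formation and degradation budget of a segment
#'
#' Sums cumulative DHA production over all DHA-forming reactions and DHA
#' loss through the three degradation channels (reaction with OH.,
#' hydrolysis to DKG, reaction with H2O2; table rows R19-R22), from the
#' flux ledger.
#'
#' @param res An `aa_segment_result` with a flux ledger.
#' @return List with `produced`, `degraded` (mol/L) and
#'   `fraction_degraded` (0-1 scale).
#' @export
dha_budget <- function(res) {
  if (is.null(res$extents)) stop("segment was integrated without a flux ledger")
  mech <- res$mech
  st <- .extent_matrix(mech)["DHA", ]
  base <- reaction_ids(mech, base = TRUE)
  ext <- res$extents[nrow(res$extents), ]
  produced <- sum(ext * pmax(st, 0))
  deg <- base %in% c("R19", "R20", "R21", "R22")
  degraded <- sum(ext[deg] * pmax(-st[deg], 0))
  list(produced = produced, degraded = degraded,
       fraction_degraded = if (produced > 0) degraded / produced else 0)
}

#' Conserved-moiety drift over a trajectory
#'
#' Computes, for every moiety group (iron, copper, ascorbate, sulfate,
#' chloride, phosphorus, probe), the maximum relative drift of the total
#' moiety concentration over the integrated trajectory.  Metals are never
#' created or destroyed by the mechanism, so their drift measures pure
#' integration error.
#'
#' @param res An `aa_segment_result`.
#' @return Named numeric vector of maximum relative drifts (groups with a
#'   zero initial total are reported as absolute drift in mol/L).
#' @export
conservation_report <- function(res) {
  mech <- res$mech
  moieties <- aa_moiety_names()
  counts <- as.matrix(mech$species[, moieties])
  totals <- res$conc %*% counts
  drift <- numeric(length(moieties))
  names(drift) <- moieties
  for (i in seq_along(moieties)) {
    m0 <- totals[1, i]
    dev <- max(abs(totals[, i] - m0))
    drift[i] <- if (m0 > 0) dev / m0 else dev
  }
  drift
}

# ---- result export ----------------------------------------------------------

#' Export a segment trajectory as CSV / its flux ledger as JSON
#'
#' The CSV has a `time_s` column plus one column per species (mol/L).  The
#' ledger JSON maps reaction id to cumulative extent (mol/L) at the end of
#' the segment.
#'
#' @param res An `aa_segment_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segment_csv <- function(res, path) {
  stopifnot(inherits(res, "aa_segment_result"))
  out <- data.frame(time_s = res$times, res$conc, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_csv
#' @export
write_ledger_json <- function(res, path) {
  stopifnot(inherits(res, "aa_segment_result"))
  if (is.null(res$extents)) stop("segment was integrated without a flux ledger")
  ext <- as.list(res$extents[nrow(res$extents), ])
  jsonlite::write_json(ext, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
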