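---
title: "Modelling ascorbate oxidation by iron, copper and reactive oxygen species"
author: "ascorbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ascorbate oxidation by iron, copper and reactive oxygen species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascorbox)
```

## The chemical problem

Ascorbic acid is the most abundant water-soluble antioxidant in lung
lining fluid, and its consumption is one of the acellular assays used to
quantify the oxidative potential of particulate matter.  Micromolar
dissolved iron and copper oxidize it far faster than reactive oxygen
species (ROS) do, but the literature disagrees about the mechanism
(catalytic versus redox), the stoichiometry and the rate constants of the
metal reactions.  `ascorbox` implements a box model of this chemistry: a
~95-row aqueous mechanism (ascorbate acid--base and radical chemistry, the
three DHA degradation channels, ROS interconversions, Fenton chemistry,
and the hydroxo/sulfato/chloro speciation of Fe(II)/Fe(III)/Cu(II)/Cu(I)),
plus the machinery needed to confront it with dose--response measurements
of dehydroascorbic acid (DHA), the two-electron oxidation product.

The central mechanistic object is the metal--ascorbate--oxygen step.  In
the catalytic family with 1:1:1 stoichiometry,

$$\mathrm{M + AH_2/AH^- + O_2 \rightarrow M + DHA + H_2O_2\ (-H^+)},$$

the metal acts as an electron bridge and keeps its valence, oxygen is
consumed stoichiometrically and hydrogen peroxide is produced.  In the
redox alternative the metal is reduced and the ascorbate radical
$\mathrm{A^{\cdot-}}$ is formed.  `build_ascorbate_mechanism()` exposes both,
plus the two fractional-order copper laws from the older literature
($k[\mathrm{Cu}][\mathrm{AH^-}][\mathrm{O_2}]^{1/2}$ and
$k[\mathrm{Cu}][\mathrm{AH_2{+}AH^-}]^{1/2}[\mathrm{O_2}]^{1/2}$), and a
mixed catalytic+redox variant used for mechanism discrimination.

## Encoding choices

**Reversible rows.**  Every reversible table row is split into separate
forward and backward irreversible reactions.  Where forward and backward
constants are both known they are used directly (and cross-checked
against the tabulated equilibrium constant to 1%).  Rows known only through
an equilibrium constant are treated as fast equilibria: the backward
constant defaults to `fast_kr` and the forward constant is
`Keq * fast_kr`.  We use `fast_kr = 1e3` (per second, or scaled by
molarity for higher molecularity).  This keeps speciation equilibration
at least five orders of magnitude faster than any competing chemistry
(the fastest consumption of a speciated reservoir in the assay scenarios
is below $10^{-2}\,\mathrm{s^{-1}}$) while keeping the cumulative extents
of these equilibria within a few orders of magnitude of the
concentrations they shuttle.  A diffusion-limited choice such as
$10^{10}$ would change no observable concentration, but it would make the
equilibrium extents reach $10^4$--$10^6$ mol/L over a 20-minute coil, and
relative-tolerance error control on extents of that size destroys the
flux ledger (and, in extent coordinates, the reconstructed
concentrations) by catastrophic cancellation.  The exported
`split_equilibrium()` helper keeps the conventional fast default of
`1e10` for standalone use.

**Protons.**  Rows written with net proton consumption ("$-\mathrm{H^+}$"
products) are rewritten with $\mathrm{H^+}$ on the reactant side at zero
kinetic order: the notation expresses a proton budget, not a kinetic
order, so the tabulated rate expression is preserved while the reaction
balances.  Backward halves of acid--base equilibria do carry first-order
$[\mathrm{H^+}]$ -- that is what makes speciation pH dependent.

**Lumped species.**  Rate constants quoted for lumped species
(Fe(III)\*\*, Fe(III)\*, Fe(II)\*, Cu(II)\*) are expanded into one
reaction instance per complex, all sharing the single constant, with the
complex's ligands released on transformation so that the sulfate and
chloride budgets close.  Upper-limit cells ("< 1e3") use the tabulated
bound as the value.

**The R6/R8 split.**  The superoxide/hydroperoxyl oxidations of
AH$_2$/AH$^-$ are experimentally inseparable; only the combination
$(w\,k_6 + k_8) = 1.22\times 10^7$ with
$w = K_a(\mathrm{HO_2^\cdot})/K_a(\mathrm{AH_2}) = 0.200$ is constrained.
Because $w$ is the pH-independent speciation ratio
$[\mathrm{AH_2}][\mathrm{O_2^{\cdot-}}]/([\mathrm{AH^-}][\mathrm{HO_2^\cdot}])$,
*any* split satisfying the constraint yields identical dynamics and
identical total ROS-pathway flux at every pH.  We set $k_6 = 0$ and
$k_8 = 1.22\times 10^7$.

**Condition-dependent constants.**  The Fe(II) + O$_2$ constant is a
lookup in (pH, temperature): $10^{-5}$ M$^{-1}$s$^{-1}$ below pH 4 at
room temperature, 0.11/0.17 at pH 6.0/6.5 (linear between), 0.39 at pH 7,
everything tenfold faster at 37&nbsp;°C, log-linear between anchors.  DHA
hydrolysis is $5.8\times10^{-4}\,\mathrm{s^{-1}}$ above pH 6, zero below
pH 4, and linear in pH between -- the shape of the ramp in the
4--6 window is not constrained by data, and no assay scenario sits inside
it.  Dissolved oxygen is initialized at air saturation for the segment
temperature ($2.58\times10^{-4}$ M at 25&nbsp;°C, $2.10\times10^{-4}$ M
at 37&nbsp;°C, linear in between); the reactor is closed, which is what
produces the oxygen-limited DHA plateaus.

**Redox defaults.**  The redox variant's constants are not a coherent
tabulated set; the defaults (Fe+AH$_2$ 66, Fe+AH$^-$ 10, Cu 880
M$^{-1}$s$^{-1}$) are nominal literature values intended as starting
points for fitting, not as calibrated parameters.

## Numerics

The mass-action ODEs are integrated with `deSolve::lsoda` through a
compiled right-hand side with an analytic Jacobian.  Two state layouts
exist.  With `ledger = FALSE` the species concentrations are the state
(about 60 equations; a full 20-minute coil takes ~10 ms), which is what
the fitting loops use.  With `ledger = TRUE` the integration runs in
reaction-extent coordinates: the state is the vector of cumulative
per-reaction extents $e$ and concentrations are reconstructed as
$c = c_0 + N e$ with $N$ the stoichiometry matrix.  This makes the
flux-ledger bookkeeping identity exact by construction, which is what the
pathway-attribution and DHA-budget analyses rest on.

pH is clamped by default ($[\mathrm{H^+}]$, $[\mathrm{OH^-}]$ fixed at
the buffered value); a dynamic mode integrates protons explicitly and is
available for unbuffered questions, at considerable extra stiffness.
Default tolerances are `rtol = 1e-8`, `atol = 1e-16` M, which resolves
sub-nanomolar radicals against $10^{-4}$ M reservoirs; fitting uses
`1e-6`/`1e-14`, whose effect on the readout (&lt; 0.01 µM) is far below
measurement noise.  Integer-order rate terms are evaluated as smooth
polynomials even for the integrator-noise-scale negative excursions that
stiff solvers produce near depletion (they self-correct); only
fractional-order terms clip at zero.  Hard clipping everywhere makes the
right-hand side non-smooth exactly where oxygen runs out and stalls the
solver on the copper pH 7 runs.

A pure-R assembly of the same rate laws (`assemble_rhs()`) is kept as an
independent cross-check of the compiled core and as the
tighter-tolerance integration oracle in the tests.

## The two-coil instrument

`run_protocol()` reproduces the online assay: a 1.1 mL/min stream of
200 µM ascorbic acid meets an equal metal stream (coil-1 concentrations
are therefore half the stream concentrations; 100 µM total ascorbic
acid), reacts 20 min at 37 °C in coil-1 (pH 2.8 with HCl, contributing
1.6 mM chloride, or pH 7 with HEPES), then meets 1.1 mL/min of oPDA
reagent (46 mM in 0.1 M HCl at pH 2.8; 20 mM for pH 7 runs), a further
2/3 dilution, and derivatizes 10 min at room temperature.  The readout is
the DHA--oPDA adduct (plus residual free DHA) at the coil-2 exit.  Coil-2
is clamped acidic (pH 2.8 for acidic runs, pH 2.0 for pH 7 runs, where
the carried HCl overwhelms the HEPES buffer), which halts DHA hydrolysis
during derivatization.  At the coil-2 oPDA concentration the
derivatization time constant is ~14 s, so the 10-minute coil completes
the reaction; doubling its length changes the readout by under 2%.

Two readout bases are supported because the reported theoretical maximum
(100 µM) refers to the coil-1 ascorbic acid concentration while the
measurement is physically made in coil 2: `"coil1"` (default) divides the
coil-2 value by the 2/3 dilution; `"coil2"` reports the concentration as
measured.  Fe(II) experiments model the stock solution's aging: a 1 mM
FeSO4 stock at its native pH ~6.3 oxidizes at ~13%/h
(`age_fe2_stock()`), and dose--response runs assume 10% of the nominal
Fe(II) is already Fe(III).

## Fitting

The objective is the sum over (metal, pH) datasets of the per-dataset
mean squared DHA error in µM².  Model predictions add the same constant
background (default 2.8 µM) that the synthetic generator adds, so a
noise-free dataset scores zero at its generating constants.

`grid_search_2d()` evaluates an 11×11 grid in $\log_{10} k$ (default box
$[2, 9]$ per axis), scores the 10×10 unit squares by their four-corner
mean MSE, and refines recursively for four cycles.  One design point
deserves note: recursing into the *best-scoring square* loses the
optimum when the two constants are correlated.  On the joint copper fit
the MSE surface is a narrow diagonal valley, and the square whose corners
average lowest need not contain the minimum -- with noise-free synthetic
data the literal square-recursion missed $k_{16}$ by 18%.  The
refinement region is therefore the box centered on the best *evaluated
grid point* with a half-width of one grid spacing, so the running
optimum always stays interior; the box shrinks fivefold per axis per
cycle ($5^4 = 625$ overall; final grid spacing ~$1.1\times10^{-3}$
log units).  The four-corner square scores are retained to flag searches
pressed against the initial bounds.  Ties resolve toward the smallest
grid indices, so the search is fully deterministic.

`coordinate_search()` handles one to four free constants: from a seeded
random start it scans one constant at a time over the current range
(21 points per axis by default), keeps the scan minimum, halves the range
when a full cycle brings no improvement, and stops when the range falls
below the requested precision (0.01 log units by default).  Its MSE
trace is monotone and reproducible from the seed.
`compare_rate_laws()` fits each rate-law variant to the same data and
ranks the variants by their best achievable MSE.

## Synthetic data

No raw measurements ship with the package (the underlying DHA measurements exist
only as figure points), so all parameter-recovery work runs against
synthetic datasets.  `generate_dose_response()` evaluates the full
two-coil model over a concentration grid and adds a 2.8 µM background
offset -- the observed blank DHA level -- plus truncated Gaussian noise
(additive σ in µM and/or a multiplicative fraction of the readout; the
replicate-level scatter in the source figures is not tabulated, so the
default σ = 1 µM is a nominal stand-in).  The generator emulates the
measured curves' shape, background and noise scale; it does not emulate
instrument drift, fluorescence calibration error, or day-to-day stock
aging variability, so passing recovery tests demonstrate the estimator's
correctness on the model's own terms, not robustness to those real-world
error structures.

Default study conditions used throughout (and by the analysis scripts):
coil-1 metal grid {2.5, 5, 10, 25, 50, 100} µM within the assay's
analyzed 0--200 µM range, both pH 2.8 and pH 7 copper datasets fitted
jointly, 5% multiplicative noise for the noisy-recovery checks.

## What the scenario analyses compute

*Pathway attribution* integrates coil-1 with the flux ledger and divides
cumulative AH$_2$/AH$^-$ consumption through the metal-catalysed rows
(R14--R17) by consumption through the ROS rows (R4--R9).  For Fe(II) at
pH 2.8 this model yields 14.5 at 2.5 µM and 1.58 at 200 µM nominal
Fe(II).  The ratio is controlled almost entirely by the Fenton conversion
of catalytically produced H$_2$O$_2$ and is insensitive to the dosing
assumptions (both pathways scale with Fe(III)), so these values are
intrinsic to the tabulated rate constants as encoded here.  *The DHA
budget* divides cumulative DHA loss through the three degradation
channels by cumulative DHA formation; for Fe(III) at pH 7 coil-1 the
model gives 28.2%, dominated by hydrolysis -- close to the value expected
from the hydrolysis constant alone under near-linear DHA formation
($1 - (1 - e^{-kT})/kT \approx 0.28$ for $kT = 0.70$).

*Hydroxyl-radical scenarios* (`run_oh_scenario()`) add the benzoate
probe and phosphate buffer chemistry and report cumulative gross OH·
production -- the summed extents of all OH·-producing reactions -- rather
than a probe-adduct yield, because trapping efficiencies of the
literature assays are not specified.  The shipped Charrier-like and
Lin--Yu-like templates reproduce the metal dose, pH regime and reaction
time of those studies but not their full matrices (which are not tabulated);
they are editable starting points, labelled as synthetic stand-ins.
Switching the catalytic product channel from DHA + H$_2$O$_2$ to
A$^{\cdot-}$ + HO$_2^\cdot$ raises cumulative OH· by far more than an
order of magnitude, which is the model's basis for preferring the
peroxide channel.

## Problem sizes and limitations

The test suite and the acceptance script run the full mechanism
(~170 irreversible reactions after splitting and lumping, ~60 species);
ledger integrations of a 20-minute coil take seconds, species-state
integrations ~10 ms, a full four-cycle grid recovery (484 objective
evaluations × 12 dataset points × 2 coils) about two minutes.  Shorter
durations or reduced grids are used where a property does not depend on
the full length, and are noted inline.

Known limitations: activity coefficients and ionic-strength corrections
are not applied; temperature dependence exists only where the source
tables state it (Fe(II) + O$_2$ and oxygen solubility); the elementary
steps behind the overall catalytic rate laws are not resolved; Fe(IV) as
an alternative Fenton product is not modelled; and the flow reactor is
treated as a sequence of well-mixed closed segments (no dispersion or
gas exchange).
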