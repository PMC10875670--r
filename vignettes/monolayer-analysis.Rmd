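---
title: "Monolayer analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monolayer analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofilm)
```

`monofilm` analyzes lipid Langmuir monolayers along two tracks: the
thermodynamics of compression isotherms, and structural observables of
monolayer molecular-dynamics configurations. This vignette documents the
underlying models, every numerically consequential choice, and what the
synthetic-data generators do and do not emulate.

## The thermodynamic track

### Isotherms and their inversion

A π–A isotherm records surface pressure π (mN/m) against mean molecular
area A (Å²/molecule) during compression. `isotherm()` stores curves in
compression order (decreasing area), averages duplicate areas, clips small
negative pressures in [−0.5, 0) mN/m to zero (Wilhelmy-plate sensor noise)
and rejects anything below −0.5 mN/m rather than silently accepting it.

Several computations need the inverse A(π). Real isotherms are not
monotone in π: pressure is flat before lift-off and inside the LE–LC
coexistence plateau, and decreases past collapse. `area_at_pressure()`
therefore

* truncates the curve at the first global pressure maximum (collapse),
  because mixing integrals run over the compression branch only;
* resolves non-monotone stretches by the **first crossing from the
  large-area side**, matching the direction of compression (a query at the
  plateau pressure returns the plateau's large-area end);
* returns the first recorded area for queries below the first recorded
  pressure — the film area is taken constant at its lift-off value before
  the sensor responds. This matters because the mixing integral starts at
  π = 0 even when a recorded curve starts above 0.

### Compressional modulus and phase states

The in-plane stiffness is `Cs⁻¹ = −A (∂π/∂A)`. Differentiating
experimental data amplifies noise, so the derivative is estimated with a
Savitzky–Golay-style local polynomial fit of π(A): for each point, the 11
nearest points (windows shifted, not shrunk, at the ends) are fit with a
cubic and the fitted value/derivative at the point is used. Unlike a
classical convolution filter this least-squares formulation does not
require a uniform area grid. Window (11) and order (3) are exposed;
window 11 at typical trough sampling (a few hundred points per curve)
spans roughly 2–3 Å², narrow enough to resolve plateau edges and wide
enough to suppress 0.05 mN/m pressure noise.

Phase labels follow the classical modulus ranges: below 25 mN/m
low-density liquid, 25–50 liquid-expanded, 100–250 liquid-condensed,
above 500 solid. The literature ranges leave the gaps (50, 100) and
(250, 500]; these are labelled `intermediate` and `transitional` rather
than silently extending the named ranges — the package does not invent
boundaries the literature does not state. All interval endpoints are
closed on the named range, making the classification a total,
deterministic partition of [0, ∞).

### Feature detection

* **Lift-off**: the largest area at which the smoothed pressure first
  exceeds a threshold (default 0.5 mN/m — the criterion behind reported
  lift-off points is rarely stated, so the threshold is a parameter).
  Interpolated linearly between the bracketing points; a curve already
  above threshold at its largest recorded area returns that boundary area
  flagged as such. The estimate is non-increasing in the threshold.
* **Collapse**: the smoothed pressure at its first global maximum; exact
  ties resolve toward larger area (first reached during compression). A
  monotonically rising curve never collapsed within the experiment and is
  returned censored.
* **LE–LC plateau**: reported when Cs⁻¹ dips below a ceiling (default
  10 mN/m) between two local modulus maxima that each exceed 25 mN/m,
  i.e. both flanking branches are at least liquid-expanded stiff. Onset
  and end are the pressures where the modulus crosses the ceiling.
  Because the derivative window is centred, these crossings land a
  fraction of a window inside the horizontal plateau; on a near-ideal
  plateau the reported pressures are accurate to about 0.1 mN/m plus
  pressure noise. That detection resolution is the tolerance used in the
  package's own recovery tests; it is a property of any centred-window
  estimator, not of the data.

### Excess Gibbs energy of mixing

For a binary film the excess area at pressure π is
`ΔA(π) = A₁₂(π) − X₁A₁(π) − X₂A₂(π)`; the excess Gibbs free energy of
mixing is its pressure integral scaled to molar units,
`ΔGᵉˣᶜ = N_A ∫₀^π ΔA dπ'`. Computation stays in (mN/m, Å²) throughout and
one exact conversion constant is applied once at the end:
1 mN/m · Å² = 10⁻²³ J, so the factor is N_A × 10⁻²³ =
6.02214076 J mol⁻¹/(mN/m · Å²) (`physical_constants$unit_factor`). This
keeps the dimensional analysis auditable and avoids unit-mixing bugs.

The integral uses the trapezoid rule on a uniform pressure grid (default
step 0.1 mN/m, matched to experimental pressure resolution; higher-order
quadrature would pretend to accuracy the data do not have). The
pure-component endpoints ΔGᵉˣᶜ(0) = ΔGᵉˣᶜ(1) = 0 are identities, not
computations, and `excess_gibbs_curve()` adds them exactly.
`curve_extremum()` reports the largest-magnitude interior extremum with
ties toward smaller X₂, and `stoichiometry_from_fraction()` searches
integer pairs (n₁, n₂) with n₁+n₂ ≤ 12 — larger denominators stop being
physically interpretable as a surface complex — preferring the smallest
total on ties, so X₂ = 0.25 gives 3:1, not 6:2.

## The structural track

Configurations are read from multi-model PDB (CRYST1 box, MODEL/ENDMDL
frames) or extended-XYZ (lattice in the comment line; only orthorhombic
lattices are accepted). Atom order must be constant across frames.
Electron counts are integer atomic numbers assigned from element symbols;
partial charges are deliberately ignored (integer weighting is auditable,
and charge-weighted densities are not the standard reported observable).
The PDB writer is limited by the fixed 3-decimal coordinate format; the
extended-XYZ writer keeps 10 decimals and is the round-trip-safe format.

* **Electron density profiles** histogram selected atoms' z coordinates,
  weighted by atomic number, averaged over frames and divided by the bin
  volume Lx·Ly·Δz (default bin 0.5 Å). The z origin defaults to the centre
  of mass of the water selection — the natural reference for "depth below
  the interface" statements — falling back to the atom mid-plane when no
  water is present; raw coordinates are available with
  `reference = "none"`. Binning covers all atoms, so the profile integral
  times the box cross-section reproduces the total selected electrons
  exactly (the conservation test asserts 0.1%).
* **Radial distribution functions** use the minimum-image convention in
  all three directions (orthorhombic boxes only — the simulated monolayer
  systems are rectangular) and require rmax ≤ half the smallest box
  length. Normalization divides the mean per-centre pair count per shell
  4πr²Δr by the **mean box density** of the distributed species. For an
  interfacial system this homogeneous normalization is physically impure
  but is the common trajectory-analysis convention; the normalization
  record travels with the result so the bias is documented, and the
  running coordination number n(r) — a pure pair count per centre — is
  unaffected by it. Self-pairs are excluded when selections overlap.
* **P–N tilt angles** are measured between the tail→head vector and the
  outward leaflet normal, in [0, 180]°. Leaflets are split by the side of
  the tail atom relative to the water centre of mass, or to the mean tail
  height when no water exists (a single-leaflet synthetic system then
  counts as upper); the axis is +z for the upper and −z for the lower
  leaflet, so 0° always means "head pointing away from the water" and
  leaflet averages are comparable.
* **Torsions** are signed IUPAC dihedrals in (−180, 180]°, validated
  against an independent implementation (`bio3d::torsion.xyz`) in the test
  suite. Conformer windows are the standard rotamer ranges: synclinal
  (gauche) ±(60 ± 30)° and anti-periplanar 180 ± 30°. Windows are closed
  intervals, so the boundary values 30°, 90° and 150° belong to the named
  class — a deterministic tie-break. Angles outside both windows are
  `other`. Torsion atom quadruples are user configuration
  (`torsion_definition()`): real force fields disagree on headgroup atom
  naming, so the package does not hard-code one naming scheme.
* **Area per molecule** is the time average of Lx·Ly over the lipid count
  per leaflet.

## What the generators emulate — and what they do not

The generators provide every input with known ground truth, at the
conditions typical of the real experiments: isotherm noise σ = 0.05 mN/m
(Wilhelmy-plate scale), a DPPC-like LE-plateau-LC model (lift-off 90 Å²,
plateau at 5 mN/m between 78 and 58 Å², collapse at 55 mN/m and 42 Å²),
condensed-type linear films without plateau, a 2D ideal gas with
C = 404.6 mN/m·Å² (k_B·T at 20 °C, for which Cs⁻¹ = π identically), and a
default coordination-shell radius of 2.2 Å, a typical Na⁺–phosphate-oxygen
contact distance. Mixture generators superpose a prescribed excess-area
function (zero, constant, triangular in π, or X(1−X)-scaled) on the
mole-fraction-weighted sum of the sampled pure components and return its
closed-form pressure integral, so the integration route can be checked
against symbolic truth. The default mixture components are sampled from
lift-off downward, making A(π) globally linear and the interpolation
chain exact; the ideal-mixing null is then recovered *exactly* (to the
last bit), not merely to integration tolerance.

These are oracles, not simulations. The piecewise-linear isotherm models
have kinks a real film does not; smoothing-based estimators are therefore
compared to analytic derivatives only away from kinks. Slab, shell and
headgroup configurations have no excluded volume, no water structure, no
force field and no conformational correlations; pseudo-lipids (residue
`LIP`, atoms `P`, `N`, `C1..C4`, …) exercise the selection logic without
committing to any real naming scheme. Passing recovery tests demonstrates
the estimators are correct, unbiased and dimensionally sound — not that
real monolayers behave like the models. Observables from real trajectories
inherit all the usual MD caveats (force-field accuracy, sampling,
system-size effects) that no analysis package can remove.

Determinism: every generator takes a mandatory seed, uses one private RNG
stream (the caller's `.Random.seed` is saved and restored), and identical
seeds give byte-identical files. Pipeline runs (`run_pipeline()`) validate
their YAML configuration against a fixed schema — unknown keys anywhere are
rejected before any computation — and re-running the same configuration and
seed produces byte-identical reports.

## Problem sizes used in the tests

The shipped tests run isotherms of 100–300 points, mixtures over three
mole fractions with a 0.1 mN/m integration grid, slabs of ≤ 1000 atoms
over ≤ 20 frames, RDFs of ≤ 160 atoms over ≤ 200 frames, and headgroup
ensembles of ≤ 20 lipids. These sizes give closed-form recovery to the
stated tolerances (1% for the mixing integral, 2% for the modulus away
from kinks and endpoints, exact pair counts for RDFs) while keeping the
whole suite fast; all scale linearly or quadratically (RDF pairs) if
larger systems are analyzed.

## Known limitations

* No replicate-isotherm averaging (the combination rule used for
  replicate experimental curves is rarely reported; inputs are single
  curves).
* No equation-of-state fitting, hysteresis analysis, or excess
  entropy/enthalpy decomposition.
* Triclinic boxes, charge-weighted densities, and anisotropy-corrected
  RDF normalizations are out of scope.
* The plateau detector assumes one coexistence plateau; films with
  multiple inflections report only the dip between the outermost
  qualifying modulus maxima.
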