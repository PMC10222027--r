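---
title: "Extracting conformational distributions from vibrational optical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting conformational distributions from vibrational optical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voaconf)
```

# The workflow

Solution-phase conformational analysis of flexible glycosides by
vibrational optical activity (VOA) proceeds in stages: enumerate
low-energy conformers, compute their relative free energies and
per-conformer vibrational stick spectra (electronic-structure work that
is *outside* this package), then classify the conformers, weight them,
simulate ensemble spectra, compare with experiment, and adjust the
weights until the chiral spectra agree. `voaconf` implements everything
downstream of the quantum chemistry. This vignette records the models,
the tunable parameters, and the design decisions behind them.

# Conformer nomenclature

A conformer of a phenyl glucopyranoside is named by joining, with
slashes:

1. the **ring hydroxymethyl** pair, e.g. `G-g+`: upper-case label for
   the O6–C6–C5–O5 torsion, lower-case for H6–O6–C6–C5;
2. the **OH···O contact network** direction among the C2/C3/C4 ring
   hydroxyls: counter-clockwise `cc` or clockwise `c`;
3. the **phenyl torsion** label for C2–C1–O1–C7;
4. (gastrodin-like molecules only) the **phenyl hydroxymethyl** pair
   for C11–C10–C13–O7 and C10–C13–O7–H7.

The phenyl *tilt* dihedral C1–O1–C7–C12 is measured and reported
numerically but deliberately not encoded in the name: within each phenyl
torsion class it takes a single characteristic value, so a separate
label would carry no information.

## Torsion classification

Labels map torsion angles to the nearest of the canonical values +60°,
−60° and 180° under the circular (wrap-around) metric. We chose
nearest-neighbour assignment over fixed ±30° windows because it is total
(every angle gets a label) and parameter-free, and because observed
members of a class can sit well away from the canonical angle (phenyl
torsions near −51° are still `G-`). The decision boundaries at 0° and
±120° are genuinely ambiguous; an angle lying exactly on one is assigned
to the lexicographically first candidate label and a warning is emitted,
so the choice is deterministic and visible.

## Contact networks

A hydroxyl H···O contact is recorded when the H-to-acceptor distance is
at or below a cutoff, 2.7 Å by default. Cooperative OH···O contacts in
these molecules sit near 2.5 Å; the default adds margin for thermal
distortion and is a configuration knob, not a constant. No donor-angle
criterion is applied by default (an optional minimum O–H···O angle
filter exists but is off), keeping the rule as simple as the data
warrant.

The chain direction convention is: `cc` when donor→acceptor links run in
increasing ring position (O2H→O3, O3H→O4), `c` when decreasing. The
literature naming does not define the direction in terms of
donor/acceptor ordering, so this mapping is a package convention; it is
isolated in one function and can be inverted with
`classify_network(..., invert_convention = TRUE)` should reference
structures indicate the opposite assignment. A consistent chain needs at
least two links; links in both directions classify as `none` with a
warning.

Atom identities are always supplied by an explicit atom map (YAML/JSON,
0-based indices) and never inferred from connectivity: XYZ atom order is
arbitrary across electronic-structure codes, and a silent misassignment
would corrupt every downstream label.

# Boltzmann populations

Percentage populations follow
$w_i = 100\,e^{-\Delta G_i/RT} / \sum_j e^{-\Delta G_j/RT}$ with
$R = 8.31446\times10^{-3}$ kJ mol⁻¹ K⁻¹. "Room temperature" is fixed at
298.15 K by default. Free energies are taken as given (kJ mol⁻¹,
relative to the ensemble minimum); no thermochemistry is computed here.
The energy-window filter retains conformers within 15 kJ mol⁻¹ of the
minimum by default — the conventional pruning threshold below which no
conformer with non-negligible room-temperature population is lost — and
renormalizes the surviving energies; the minimum always survives, so the
result is never empty.

Published (transcribed) weight sets are stored verbatim with provenance
`"stated"`, including one gastrodin set whose printed percentages sum to
105 and one that covers only the adjusted conformers (sum 83).
Renormalization is available via `normalize_weights()` but is never
applied silently: preserving the printed numbers exactly is what makes
the grouped-abundance reproductions meaningful.

# Spectral simulation

## Lorentzian broadening

Stick spectra are broadened with an **area-normalized** Lorentzian of
half-width at half-height (HWHH) γ = 4 cm⁻¹:
$S(\nu) = \sum_k I_k \frac{\gamma/\pi}{(\nu-\nu_k)^2 + \gamma^2}$.
Each line then contributes integrated area $I_k$, total band intensity
is conserved, and population mixing acts on physically additive
quantities. (A peak-height convention differs only by the constant
$\pi\gamma$, but the convention must be fixed and stated; this is ours.)
The tails of a Lorentzian decay slowly — a grid extending $L$ to either
side of a line captures $1 - (2/\pi)(\gamma/L)$ of its area, so ±4000
cm⁻¹ leaves ~0.06% truncated — which matters when checking
normalization, not in the fingerprint-window comparisons the pipeline
actually performs.

Default grids are 1000–1700 cm⁻¹ for IR/VCD (the fingerprint window of
solution FTIR/VCD work on carbohydrates) and 200–2000 cm⁻¹ for
Raman/ROA (a typical ROA acquisition range), at 1 cm⁻¹ step; all are
configurable.

## Frequency scaling

Harmonic frequencies systematically overestimate observed band
positions. The correction is a linear model
$\nu_{exp} = a\,\nu_{calc} + b$ fitted by ordinary least squares to
user-supplied matched band pairs (≥ 2 pairs with distinct calculated
positions), with a plain uniform scale factor ($b = 0$) available as the
degenerate case. Per-modality models are allowed — nothing forces one
model across IR, VCD, Raman and ROA, and the default is to fit each
modality separately when separate calibration pairs are given. Scaling
maps line positions only; intensities are untouched, and a scaled
position at or below 0 cm⁻¹ is an error naming the offending line.

## Ensemble averaging

The ensemble trace is the pointwise convex combination
$\sum_i (w_i/100) S_i(\nu)$ on a shared grid. Averaging commutes with
broadening (both are linear), which the test suite asserts to 1e-12 —
a cheap, sharp internal-consistency check.

# Weight refinement

The published analyses adjust conformer weights *manually*, judging
visual agreement between simulated and experimental VCD/ROA while
respecting the computed stability ordering. We formalize that procedure
so it is reproducible:

$$\min_{w \ge 0,\ \sum w_i = 100}\;
\alpha\,(1 - S_{chiral}(w)) + (1-\alpha)\,(1 - S_{parent}(w))
 + \lambda \sum_i \frac{(w_i - w_i^{B})^2}{100^2}$$

where $S$ is the normalized overlap
$\int fg\,d\nu / \sqrt{\int f^2 d\nu \int g^2 d\nu}$ between the
weighted simulated trace and experiment. Signed spectra (VCD/ROA) are
compared as-is, so $S = 1$ requires the traces to be positive multiples
of each other and sign errors are penalized; unsigned spectra (IR/Raman)
are first aligned to a common zero baseline by subtracting each trace's
minimum, making the score offset-invariant.

Parameter choices:

* **α = 0.7** — the chiral modality dominates, because VCD and ROA
  features vary strongly between conformers while the parent IR and
  Raman traces barely move; the parent term mainly guards against
  degenerate solutions that fit the chiral trace with unphysical band
  intensities.
* **λ = 0.1** — a quadratic prior toward the Boltzmann weights encodes
  "follow the predicted stability trend unless the spectra insist
  otherwise". λ = 0 fits the spectra alone; λ → ∞ returns the Boltzmann
  weights (asserted numerically in the tests).
* Both are fixed convex mixing constants, not fitted: there is no
  training signal from which to learn them.

The simplex constraint is handled by a softmax parameterization and
minimized with BFGS from the Boltzmann starting point (optionally with
additional deterministic starts at the simplex vertices). The optimizer
is deterministic given its inputs; the returned weights are never worse
(in objective) than the starting point, and non-convergence within the
iteration cap is flagged on the result rather than raised. An
independent integer-resolution grid search over the simplex serves as
the oracle in the test suite, not as the implementation.

# Grouped abundances

`group_abundances()` sums weights by a key parsed from the systematic
names: the upper-case first label (`pyranose-hydroxymethyl`, giving the
G+:G−:T distribution) or the first three name parts (`phb-glu-core`,
for grouping gastrodin conformers by their ph-β-glu core).
`core_group_rollup()` takes core-group percentages to the G+:G−:T
distribution. Group totals equal the input total exactly — off-100
stated sets stay off-100 — and reports keep full precision: when core
percentages of 8 and 0.3 both fall in the T group the report says 8.3,
not a rounded 8 or 9 (published summaries round this number
inconsistently).

# The synthetic-data generator

The generator exists so that every stage is testable without quantum
chemistry. It emulates three artifacts:

* **Geometries**: a minimal glycoside-like scaffold placed atom by atom
  from internal coordinates (1.4 Å heavy-atom bonds, tetrahedral sugar
  angles, trigonal phenyl angles) such that every classifiable dihedral
  equals its prescribed canonical angle plus uniform jitter. Jitter is
  capped at ±15° so that nearest-canonical classification can never flip
  a label (canonical angles are 120° apart). Ring-hydroxyl hydrogens are
  aimed along the O···O axes to realize the requested `cc`/`c` chain;
  the resulting H···O distances (~1.8 Å on this idealized scaffold) are
  shorter than the ~2.5 Å typical of the real molecules but well inside
  the detection cutoff, and classification depends only on the
  threshold, not the exact distance. Atom order is fixed across
  conformers so one atom map serves a whole ensemble.
* **Stick spectra**: line positions uniform over the modality range,
  intensities uniform in (0.2, 1], chiral lines signed at random.
  Conformers draw independent positions, which makes their broadened
  spectra nearly orthogonal and the mixing weights identifiable — the
  tests verify pairwise VCD overlap < 0.9.
* **Experimental composites**: the truth-weighted broadened average plus
  additive Gaussian noise scaled to a fraction of the maximum absolute
  signal. Additive Gaussian noise is the simplest defensible stand-in;
  no instrument model is implied. Seeds are split by purpose: changing
  the noise seed never moves band positions.

What passing these tests does **not** show: that the pipeline recovers
weights from *real* spectra. Real conformer spectra are far more
collinear than independently drawn line lists (IR especially), real
noise is structured (baseline drift, solvent subtraction residuals), and
real simulated band positions carry systematic DFT error beyond a linear
map. The synthetic results demonstrate correctness of the machinery, and
the spread under 5% noise (weights recovered within ±5 over 20 seeded
replicates of the 3-conformer case) bounds the favorable-case
uncertainty only.

# Numerical choices and degenerate inputs

* Dihedrals use the IUPAC sign convention, range (−180°, 180°], computed
  via `atan2`; collinear triples raise a degenerate-geometry error
  rather than returning an arbitrary value. The reversal identity
  dihedral(l,k,j,i) = dihedral(i,j,k,l) is asserted property-style.
* Classification-boundary angles warn and resolve lexicographically (see
  above).
* Overlap integrals use trapezoidal quadrature on the shared grid;
  spectra on different grids are linearly resampled onto the overlap of
  their ranges, which must span at least 100 cm⁻¹. Zero-norm spectra
  make similarity undefined and raise an error.
* An empty stick list broadens to a zero spectrum (not an error);
  weights of exactly 100/0 reproduce a single conformer's trace
  bit-for-bit.
* All generators take mandatory seeds and restore the caller's RNG
  state.

# Problem sizes

The test suite and the acceptance script run at desk scale by design:
ensembles of 2–24 conformers, grids of ≤ 1801 points, 10–12 lines per
synthetic spectrum, 20 noise replicates, and a 1%-step simplex grid
search (5151 points) as the refinement oracle. The full suite runs in a
few seconds; nothing in the package's claims depends on larger runs.

# Known limitations

* No ring-pucker (⁴C₁ vs boat) detection, bond-connectivity perception,
  or anomer assignment from geometry: the naming scheme presumes a
  ⁴C₁ β-glycoside scaffold described by an explicit atom map.
* The `cc`/`c` direction convention is an explicit package choice (see
  above) pending a reference structure to anchor it.
* Frequency scaling is linear per modality; mode-specific or
  wavenumber-dependent corrections are out of scope.
* Intensities are arbitrary units end to end; no conversion to molar
  absorptivity, no instrument response, no solvent subtraction.
* The refinement objective is non-convex in general; the deterministic
  BFGS-from-Boltzmann strategy (plus optional vertex multi-starts) can
  in principle return a local optimum. The objective-never-worse
  guarantee and the grid-search oracle in the tests bound the damage at
  the scales exercised here.
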