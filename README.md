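# voaconf

Conformational distributions of flexible glycosides from vibrational
optical activity (VOA) spectroscopy.

## The problem

Flexible monosaccharide derivatives such as phenyl β-D-glucopyranoside
(ph-β-glu) and its para-hydroxymethyl relative gastrodin populate many
low-energy conformers in solution. Their parent IR and Raman spectra are
nearly insensitive to which conformers dominate, but the chiral VOA
spectroscopies — vibrational circular dichroism (VCD) and Raman optical
activity (ROA) — vary strongly with conformation. Comparing simulated
ensemble VOA spectra with experiment therefore lets one extract
*experimental* conformational distributions directly in solution, e.g.
the population of the exocyclic hydroxymethyl rotamers G+, G− and T.

`voaconf` implements the post-quantum-chemistry half of that workflow,
for anyone who already has (or can simulate) per-conformer free energies
and vibrational stick spectra:

1. **Classification** — systematic conformer names such as `G-g+/cc/T`:
   rotamer labels for the ring hydroxymethyl torsions
   (O6–C6–C5–O5 ≈ +60°/−60°/180° → `G+`/`G-`/`T`; H6–O6–C6–C5 →
   `g+`/`g-`/`t`), the direction of the cooperative intramolecular
   OH···O chain among the C2/C3/C4 hydroxyls (counter-clockwise `cc` or
   clockwise `c`), the phenyl torsion (C2–C1–O1–C7), and for
   gastrodin-like molecules a fourth part for the phenyl hydroxymethyl
   (C11–C10–C13–O7, C10–C13–O7–H7). Torsions classify to the *nearest*
   canonical angle under the circular metric, so a −51° phenyl torsion is
   `G-`.
2. **Populations** — Boltzmann percentages
   `w_i = 100·exp(−ΔG_i/RT)/Σ_j exp(−ΔG_j/RT)` at 298.15 K from relative
   free energies (kJ mol⁻¹), with a 15 kJ mol⁻¹ energy-window filter.
3. **Spectral simulation** — area-normalized Lorentzian broadening
   (HWHH γ = 4 cm⁻¹) of per-conformer stick spectra, linear frequency
   scaling ν_exp = a·ν_calc + b fitted by least squares to matched band
   pairs, and population-weighted ensemble averaging, for IR, VCD, Raman
   and ROA.
4. **Re-weighting** — the manual, visual re-weighting of conformer
   populations against experiment is formalized as a simplex-constrained
   minimization of
   `J(w) = α(1−S_chiral) + (1−α)(1−S_parent) + λ·Σ(w_i−w_i^B)²/100²`,
   where `S` is the normalized spectral overlap
   `∫fg / √(∫f²·∫g²)` and the Boltzmann weights act as a prior.
5. **Grouped abundances** — weight sums by hydroxymethyl rotamer
   (the G+:G−:T distribution) or by ph-β-glu core conformation for
   gastrodin.

A seeded synthetic-data generator builds geometries that realize
prescribed torsion labels, distinguishable stick spectra, and noisy
composite "experimental" spectra with known ground-truth weights, so the
entire pipeline is testable without any quantum chemistry.

## Worked example

Group the published empirical per-conformer weights of ph-β-glu in DMSO
into the hydroxymethyl distribution:

```r
library(voaconf)

w <- stated_weights("phb_glu", "dmso")
print(w)
#> <conformer_weights: stated, 8 conformers, total 100%>
#> G-g+/cc/T G+g-/cc/T  Tg+/cc/T G-g-/cc/T  G-g+/c/T  G+t/cc/T  G-t/cc/T G+g+/cc/T
#>      60.0      10.0      10.0      10.0       2.5       2.5       2.5       2.5

group_abundances(w, key = "pyranose-hydroxymethyl")
#> <distribution_report: key 'pyranose-hydroxymethyl', provenance stated>
#>  group percent
#>     G+      15
#>     G-      75
#>      T      10
```

So 75% of the ensemble holds the G− hydroxymethyl rotamer, 15% G+ and
10% T. Two near-degenerate conformers 0.3 kJ mol⁻¹ apart split almost
evenly at room temperature:

```r
boltzmann_percentages(
  ensemble_energies(c("G-g+/cc/T", "G+g-/cc/T"), c(0, 0.3)))
#> <conformer_weights: boltzmann, 2 conformers, total 100%>
#> G-g+/cc/T G+g-/cc/T
#>     53.02     46.98
```

And a synthetic geometry built for the labels (G−, g+, cc, T) with ±10°
torsional jitter re-classifies to its prescribed name:

```r
g <- make_conformer_geometry(
  list(ring_upper = "G-", ring_lower = "g+", network = "cc", phenyl = "T"),
  "phb_glu", seed = 1, jitter = 10)
assemble_name(g$geometry, g$atom_map)
#> G-g+/cc/T
```

See `vignettes/conformational-distributions.Rmd` for the model details,
parameter choices and limitations, and `inst/scripts/voaconf` for the
command-line entry point (`classify`, `populations`, `simulate`,
`reweight`, `distribution`, `synth` subcommands over a YAML config).

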