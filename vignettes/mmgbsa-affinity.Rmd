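---
title: "Predicting kinase-peptide affinity shifts with ensemble MM/GBSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting kinase-peptide affinity shifts with ensemble MM/GBSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepaffinity)
```

## The scientific problem

PKA discriminates sharply between peptide substrates that differ by a
single residue around the phosphoacceptor serine. The package implements a
protocol for rationalising and predicting that discrimination: convert the
measured steady-state kinetics of each peptide into experimental
free-energy shifts, rescore snapshot ensembles of each kinase-peptide
complex with MM/GBSA to get calculated binding shifts, and correlate the
two. The interest is in *relative* quantities — variant minus wild type —
which is what makes a fast end-state method viable at all.

## From kinetics to free energies

Two shifts are derived per peptide at T = 298.15 K (the simulation
thermostat temperature; the conversions reproduce the published shift
columns to better than 0.01 kcal/mol at this T, which is what fixes the
choice):

* `ddg_binding_from_km()`: `R T ln(KM_i / KM_WT)`. KM is treated as a
  dissociation-constant proxy under the quasi-equilibrium assumption; this
  is an assumption of the model, stated rather than hidden.
* `ddg_catalysis_from_efficiency()`: `R T ln(eff_WT / eff_i)` with
  `eff = Vmax/KM`. Because both conversions use ratios, the table units
  (uM; umol/(min mg)) cancel and no unit layer is needed.

Rows with negligible activity cannot yield finite shifts; `kinetic_table()`
rejects non-positive constants outright rather than guessing.

## The MM/GBSA engine

`snapshot_binding()` implements the single-trajectory protocol: receptor,
ligand and complex energies are all evaluated on coordinates cut from the
same complex frame, so the internal (bond/angle/dihedral) difference
cancels *exactly* — the engine asserts this and stores a literal zero. The
remaining terms:

* **Electrostatics**: Coulomb sum with constant 332.0636 kcal·Å/(mol·e²),
  no distance cutoff (cutoffs belong to the MD that produced the frames,
  which is out of scope here), 1-2/1-3 pairs excluded and 1-4 pairs scaled
  by a configurable factor (default 1.0).
* **van der Waals**: 12-6 Lennard-Jones in the rmin convention with
  Lorentz–Berthelot-style combining from per-atom half-rmin values.
* **Polar solvation**: generalized Born in the OBC-II parameterisation
  (tanh rescaling α = 1.0, β = 0.8, γ = 4.85 over HCT pairwise
  descreening, intrinsic-radius offset 0.09 Å, element-based screening
  factors) evaluated through Still's pairwise formula with
  `f_GB = sqrt(r² + R_i R_j exp(−r²/4R_iR_j))`, solvent dielectric 78.5
  over solute dielectric 1.0. The GB flavour is a genuine design choice:
  only "generalized Born at ε = 78.5" is pinned down by the protocol being
  reproduced, and OBC-II is the variant documented for the MD engine that
  protocol used. Everything is isolated behind `gb_settings()` so another
  flavour means changing constants, not code paths.
* **Nonpolar solvation**: `γ·SASA + b` with γ = 0.00542 kcal/mol/Å², b = 0
  (γ is not pinned by the protocol; this is the widely used default and is
  recorded in every report header). SASA is Shrake–Rupley quadrature on a
  deterministic golden-spiral point set (512 points/atom by default; the
  isolated-sphere error is well under 0.5%), probe 1.4 Å, with the
  intrinsic Born radii serving as the atomic radii.
* **Entropy**: carried as a field, fixed at zero — for closely related
  complexes its change is assumed to cancel in relative comparisons, and
  `energy_components()` refuses non-zero values so the assumption cannot
  drift silently.

`ensemble_binding()` averages snapshots chosen by a deterministic uniform
stride (the original protocol used 900 snapshots over 10 ns; desk-scale
runs here use tens of frames) and reports per-snapshot standard deviations,
not standard errors — the ± values it mirrors are not defined as SEM, so
the more conservative reading is used.

Parameters travel in a flat TSV keyed by (residue, atom) rather than a
force-field file format: the energy function above needs only charges, LJ
pairs, Born radii and bonded constants, and a minimal schema keeps fixtures
hand-writable. Lookups must be complete; a missing atom is an error naming
the offender, never a silent default.

## Ensemble analysis

Hydrogen bonds use the distance-only criterion the protocol states:
donor–acceptor *heavy-atom* distance < 3.5 Å, no angle term. This is
weaker than DSSP-style definitions and is documented as such; hydrogens,
if present, are stored but not consulted. Occupancy uses the full frame
count as denominator while the conditional mean ± SD distance uses only
the qualifying frames — two deliberately different denominators,
implemented explicitly. "Stable" means occupancy ≥ 50%. Published tables
of this kind occasionally pair high occupancies with conditional mean
distances above the cutoff; `stable_interactions()` therefore recomputes
both and drops such rows by default (`include_over_cutoff = TRUE` keeps
them for comparison). Hydrophobic contacts reuse the machinery at a
C–C cutoff of 4.5 Å, restricted to carbon atoms.

RMSD is measured after Kabsch superposition (SVD with a determinant guard
against improper rotations) on the same selection, default backbone
(N, CA, C, O), against the first post-equilibration frame.
`enumerate_candidate_pairs()` pre-screens receptor–ligand pairs; with the
default stride of 1 its output is a strict superset of every pair that
ever qualifies at the analysis cutoff, and that guarantee is
property-tested.

## The correlation layer

`squared_pearson()` defines R² as the squared Pearson correlation, which
coincides with the OLS coefficient of determination with intercept — the
two common readings agree here, and the choice is recorded. The
experimental axis is the catalysis shift, the calculated axis the binding
shift; R² is symmetric in the axes, so the assignment only affects how
slope and intercept are reported.

Histidine mutants are modelled as Hδ, Hε and Hp. `select_histidine_pair()`
evaluates all nine (position 18) × (position 19) assemblies — each is the
wild type (which anchors every cell at (0, 0)), the four non-histidine
mutants, and one histidine model per position — and reports the argmax; ties
are all reported rather than silently broken. On the bundled tables the
best cell is Hε@18 with Hp@19 (R² = 0.710), every cell clears 0.6, and
adding the three shorter peptides gives the full ten-point model
(R² = 0.714). The package recomputes the experimental shifts from the raw
kinetics rather than consuming pre-rounded shift columns; both routes agree
to 3 decimals on all three R² values.

```{r correlation}
corr <- run_correlation()
round(corr$grid$grid, 3)
corr$full
```

## The synthetic-data generator

`make_toy_complex()` builds a parameterized mini receptor strand plus
peptide with dedicated donor/acceptor contact atoms at prescribed
separations and charges; toy parameters sit in common force-field ranges
(charges within ±0.5 e with contact charges up to ±1 e, LJ ε 0.05–0.2
kcal/mol, radii 1.2–2.0 Å). Bond and angle equilibria equal the built
geometry, so the reference conformation is strain-free and any bonded
energy in a frame is pure noise displacement. `make_ensemble()` adds
isotropic Gaussian noise and then *constructs* each scheduled
hydrogen-bond occupancy by placing the pair distance inside or outside the
cutoff in a seeded shuffle of frames: realised occupancies equal targets
exactly, so tests are sharp instead of binomially fuzzy (a sampled mode
exists behind `exact = FALSE` for realism checks). Bound distances are kept
clear of the cutoff on both sides so noise cannot flip a frame across it;
pairs sharing atoms, or targets that are not integer frame counts, are
rejected as contradictory rather than approximated.

What the generator does *not* emulate: real conformational dynamics,
correlated motions, solvent structure, or the actual kinase/peptide
geometry. Passing tests therefore demonstrate that the estimators and
energy kernels are correct on data with known ground truth — not that the
force-field or GB parameterisation reproduces any particular experimental
system.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear fit atoms; collinear input is a
  hard numerical-degeneracy error (checked via the second singular value).
* Coincident atoms in an interacting pair are singularities (Coulomb, LJ)
  or model-validity errors (Born radii), reported as such.
* An isolated atom's effective Born radius is its offset-corrected
  intrinsic radius (radius − 0.09 Å); with `radius_offset = 0` it equals
  the intrinsic radius exactly. Both limits are unit-tested.
* Snapshot selection, sphere quadrature points and candidate-pair
  enumeration are all deterministic; the only randomness in the package is
  in the generators, and every generator requires an explicit seed and
  restores the caller's RNG state.
* Grid ties in tautomer selection and duplicate schedule atoms are
  reported/rejected, never resolved by an arbitrary pick.

## Problem sizes

The bundled tables are complete (10 peptides, 11 + 4 energy rows). The
synthetic stages of the test-suite and the acceptance script use complexes
of ~20–30 atoms and ensembles of 8–200 frames — sizes chosen so each
oracle comparison (closed forms, quadrature integrals, brute-force
quaternion searches) runs in seconds while still exercising every code
path at meaningful signal-to-noise.

## Known limitations

* One row of the bundled mutant energy table (R18K) is internally
  inconsistent: its components sum to −58.23 kcal/mol against a stated
  total of −59.32. The table ships verbatim and
  `check_component_sums()` flags the row; its ΔΔG column (which is what
  the correlation layer consumes) is consistent with the stated total.
* Absolute MM/GBSA values computed here for synthetic systems are not
  comparable to the bundled reference energies — those derive from long
  explicit-solvent trajectories of the real kinase with a specific GB
  parameterisation. The package's claim is kernel correctness and
  faithful relative comparisons, not reproduction of absolute ensemble
  energies.
* The distance-only hydrogen-bond criterion over-counts relative to
  angle-aware definitions; occupancies are comparable within the package,
  not across tools.
* No entropy, no explicit solvent, no periodic boundary conditions, no
  Poisson–Boltzmann reference solver: all are out of scope by design.
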