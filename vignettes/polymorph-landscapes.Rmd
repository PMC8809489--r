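---
title: "Analysing crystal energy landscapes of conformational polymorphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing crystal energy landscapes of conformational polymorphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscape)
```

## The problem

Crystal structure prediction (CSP) for a flexible organic molecule produces
hundreds of candidate packings, each with a lattice energy from some model
chemistry. For conformational polymorphs — molecules such as ROY whose
polymorphs differ mainly in one torsion angle θ — generalized-gradient DFT
models suffer from delocalization error: conformations with more extended π
conjugation (flatter θ) are spuriously stabilised, so the ranking of
candidates by lattice energy is systematically skewed toward planar
conformers. `polyscape` implements the post-search analysis pipeline for such
landscapes:

1. **Monomer conformational-energy correction.** The corrected energy per
   unit cell replaces the crystal model's intramolecular energy with a
   higher-level gas-phase monomer energy:

   $$E_\mathrm{corr} = E_\mathrm{crystal}^{\,\mathrm{base}}
     + \sum_i m_i\,\bigl(E_{\mathrm{mon},i}^{\,\mathrm{target}}
     - E_{\mathrm{mon},i}^{\,\mathrm{base}}\bigr),$$

   where $i$ runs over the symmetrically unique monomers in the cell (in
   their crystalline geometries) and $m_i$ is the number of symmetry copies
   of monomer $i$, so that $\sum_i m_i = Z$. All downstream comparisons are
   per molecule ($E_\mathrm{corr}/Z$); this is the only normalisation that
   puts $Z' = 1$ and $Z' = 2$ forms on one axis.

2. **Ranked energy–density landscapes** with energy-window queries,
   packing-similarity deduplication, and labelling of candidates against
   experimental reference structures.

3. **Pressure screening** via $H = E_\mathrm{latt} + PV$ (phonon and thermal
   contributions neglected), with crossover-pressure detection and an
   optional Birch–Murnaghan equation-of-state layer.

4. **Conformation analysis**: the key S–C–N–C torsion, polymorph color
   classification and basin assignment.

## Conventions and tunable parameters

* **Torsions** are reported as $|\theta| \in [0, 180]$ degrees; the sign
  carries no information for the color/basin questions asked here, and the
  absolute-value convention makes the classification invariant under mirror
  images.
* **Color**: yellow iff $50^\circ \le \theta \le 130^\circ$, otherwise
  red/orange. The literature describes the yellow window only approximately
  (∼90 ± 40°), and does not state whether its edges are inclusive; the
  boundaries used here are therefore *declared*, with ties assigned to the
  yellow side so the rule is deterministic.
* **Basins**: A iff $\theta < 80^\circ$, else B; the boundary 80° is
  assigned upward. The split mirrors the barrier near 80° in the gas-phase
  conformational profile.
* **Bond perception** uses covalent-radius sums scaled by a tolerance of
  1.2 under the minimum-image convention — the standard crystallographic
  heuristic. Hydrogens bond only to their nearest heavy atom. Partial
  occupancies are rejected rather than silently handled: landscape
  structures are fully ordered, and a disordered input is a user error worth
  surfacing.
* **Cluster RMSD** (`rmsd_n_cluster`): an $n$-molecule cluster (default
  $n = 15$) is built around a central molecule — the one nearest the cell
  centroid, which removes any dependence on arbitrary site ordering — plus
  its $n-1$ nearest neighbours by centroid distance across periodic images.
  Every symmetry-distinct molecule of the second structure is tried as the
  matching center (capped at 12 candidates nearest the cell interior;
  translationally equivalent molecules give identical clusters, so more
  candidates are redundant). The two clusters are oriented by superposing
  their central molecules, molecules are paired greedily by nearest
  centroid within a fraction (`distance_tol`, default 0.25) of the
  nearest-neighbour centroid spacing, and one refinement pass re-pairs under
  the full-cluster fit. Hydrogens are excluded from the RMSD and inversion
  (enantiomorph) matching is on by default, following conventional
  packing-similarity practice. An incomplete pairing returns
  `n_matched < n` rather than an error.
* **Deduplication** merges entries that agree in energy
  (`energy_tol = 0.5` kJ/mol per molecule) *and* packing
  (`rmsd_tol = 0.3` Å over a full $n$-molecule match). The merge keeps the
  lower-energy member and is idempotent. The defaults are declared choices:
  how duplicates were pruned in published landscapes is typically not
  stated.
* **Pressure**: the PV term uses 0.602214076 kJ/mol per GPa·Å³ (Avogadro's
  number scaled to these units). Enthalpy–pressure curves are interpolated
  with a shape-preserving monotone piecewise cubic (Fritsch–Carlson), which
  cannot overshoot between samples — important because crossover detection
  must not ring. Extrapolation beyond 5% of the sampled pressure range is a
  hard error, not a warning: high-pressure claims beyond the sampled regime
  are not trustworthy. Crossovers are genuine sign changes of ΔH(P) located
  by bracketing and bisection to $10^{-4}$ GPa; stretches where two phases
  are exactly degenerate are not reported as crossings.
* **Units** are fixed at the I/O boundary to kJ/mol, Å, Å³, GPa and g/cm³;
  converters from hartree and eV (CODATA factors) are provided.

## What the synthetic generator emulates — and what it does not

`generate_landscape()` produces a fully specified toy landscape so that every
pipeline stage can be validated against known ground truth without any
electronic-structure back-end:

* Each structure hosts a rigid 10-heavy-atom molecule with exactly one
  S–C–N–C path whose torsion is planted exactly (internal-coordinate
  construction).
* True per-molecule energies are a double well
  $w(\theta) = w_0 \sin^2 2(\theta - \theta_0)$ (defaults $w_0 = 6$ kJ/mol,
  $\theta_0 = 45^\circ$: minima near 45° and 135°, barrier near 90°,
  qualitatively matching the two-basin conformational profile) plus a
  packing term — a seeded uniform spread of up to 12 kJ/mol across the
  landscape with a configurable noise component of standard deviation
  `packing_noise`. The packing term is drawn, not computed from a potential:
  the pipeline under test consumes energies, it does not need them to be
  physical.
* The biased "base" model subtracts $\delta \cos^2\theta$ per molecule — the
  form that maximally stabilises planar conformations ($\theta \to 0$ or
  $180^\circ$), mirroring the direction of delocalization error. Any
  θ-dependent form the monomer correction can cancel would serve; this one
  is the documented choice. Matching monomer pairs satisfy
  $E^\mathrm{target}_\mathrm{mon} - E^\mathrm{base}_\mathrm{mon}
  = \delta\cos^2\theta$ exactly, so the correction removes the bias
  *identically*: corrected per-molecule energies equal the generator's truth
  to floating-point precision, and the corrected Spearman correlation with
  the true ranking is exactly 1. The replicate-based ranking-improvement
  property is therefore a directional check (corrected ≥ base), with the
  interesting variation living in how badly the bias scrambles the base
  ranking.
* Torsions are drawn from a configurable mixture (default: truncated
  normals at 45° and 135° with σ = 25°, weights 0.45 each, plus a 10%
  uniform component), giving both basins and planar-rich tails.
* Duplicates are planted as jittered copies (Gaussian, `jitter = 0.05` Å
  per coordinate) sharing their parent's energies, so tolerance pairs
  (`rmsd_tol`, `energy_tol`) bracketing the jitter must recover the planted
  partition exactly.
* Crystals are generated in P1 (Z = 1) or P2₁ (Z = 2) with randomized cells
  (edges 12–15 Å) and a hard intermolecular heavy-atom contact floor of
  2.5 Å, by rejection sampling.

What the toys do **not** emulate: realistic packing energetics, many-body
polarisation, special positions and disorder, Z′ > 2, space-group diversity
beyond P1/P2₁, or the actual conformational profile of any real molecule.
Passing tests on synthetic landscapes therefore validate the *bookkeeping
and numerics* of the pipeline — Eq.-style correction arithmetic, ranking,
matching, dedup, crossover detection — not the chemistry of any particular
energy model.

## Numerical choices and degenerate inputs

* Energy ties on a landscape are broken lexicographically by structure id,
  making ranks deterministic.
* Window queries are boundary-inclusive (`rel_energy <= window`), matching
  the natural reading of "within an energy window".
* The correction guards against double application: records carry a
  `corrected` flag, and correcting twice is an error.
* Reading a CIF requires cell, symmetry (explicit operations preferred; a
  bundled Hermann–Mauguin table of common molecular-crystal settings as a
  fallback) and fractional sites; fractional coordinates are reduced to
  [0, 1) and identity is always the first operation.
* `detect_zprime` reports what the file contains
  (`z_total / |ops|`); it does not adjudicate conflicting literature claims
  about any particular form's Z′.
* The Birch–Murnaghan fit needs ≥ 4 samples spanning ≥ 10% in volume;
  starting values come from the sample minimum and a quadratic-curvature
  estimate of $B_0$.

## Worked example

```{r example}
cfg <- synthetic_config(n_structures = 30, bias_strength = 10,
                        packing_noise = 1, duplicate_fraction = 0.1,
                        seed = 42)
gen <- generate_landscape(cfg)

recs <- correct_records(gen$records)
ls <- build_landscape(recs, gen$structures)
head(as.data.frame(ls)[, c("structure_id", "rel_energy", "theta",
                           "color_class", "rank")])

# the biased base model vs the corrected landscape
base <- gen$truth$e_base_cell / gen$truth$z_total
cor(base, gen$truth$e_true_per_molecule, method = "spearman")
e_corr <- vapply(recs[gen$truth$structure_id],
                 function(r) r$e_per_molecule, numeric(1))
cor(e_corr, gen$truth$e_true_per_molecule, method = "spearman")

# deduplicate with the default tolerances
dd <- deduplicate(ls, gen$structures)
nrow(dd$merges)
count_in_window(dd$landscape, 10)
```

```{r pressure}
p <- seq(0, 15, by = 0.1)
y <- pv_series("Y", p, rep(-100, length(p)), 300 - 2 * p)
s15 <- pv_series("s15", p, rep(-96.4, length(p)), 298.8 - 2 * p)
crossover_pressure(relative_enthalpy_curve(s15, y, p))
```

A structure 3.6 kJ/mol above the reference but 1.2 Å³ denser per molecule
crosses to the stable side near 5 GPa — the arithmetic behind screening
dense, slightly metastable candidates as high-pressure polymorph
predictions.

## Problem sizes used in the shipped checks

The package's own validation uses landscapes of 30–100 structures,
50-structure dedup problems with 20% planted duplicates, clusters of 15–20
molecules (up to ~200 heavy atoms in the jitter calibration, where the mean
fitted RMSD over 100 replicates is compared against the σ√3 expectation),
and 100-replicate ranking studies. These sizes were chosen to exercise every
code path at full fidelity while keeping the whole suite comfortably fast on
a laptop.

## Known limitations

* The CIF subset has no support for multi-line text fields, disorder,
  or site-symmetry multiplicities beyond explicit operation lists and the
  bundled space-group table.
* Molecule matching in `rmsd_n_cluster` assumes the two structures store
  chemically identical molecules with consistent atom ordering (true for
  anything the package writes); arbitrary external pairs with permuted atom
  order would need a graph-canonicalisation layer that is out of scope.
* Greedy centroid pairing can in principle fall into a suboptimal
  assignment for pathological clusters with many degenerate centroid
  distances; the refinement pass and the multi-center search make this rare
  in practice, and a failed pairing is reported (`n_matched < n`), never
  silently wrong.
* Enthalpies neglect phonons and thermal effects throughout, by design.
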