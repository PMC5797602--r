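---
title: "Methods: contact, ion-atmosphere and energetic analysis of protein–RNA complexation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, ion-atmosphere and energetic analysis of protein–RNA complexation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexion)
```

## The system and the model

The package targets a specific physical situation: a long, intrinsically
disordered polyampholyte protein (the reference composition is a
284-residue chain with 47 D, 24 E, 18 K and 9 R — net charge −44 at
physiological pH, with −26 of it in the first 100 residues) approaching a
~40-nucleotide RNA stem-loop that exposes a high density of phosphate
charge (−39 for a 40-mer with a free 5′ hydroxyl). Na⁺, Mg²⁺ and Cl⁻
counterions mediate the association: divalent cations adsorb onto the
phosphate oxygens, monovalent cations condense diffusely, and cations
simultaneously coordinated by both partners act as salt bridges.

Everything the package computes is a *descriptor* of configurations, never
a propagator of them: inputs are structures or trajectory snapshots
produced elsewhere (or synthesized by the package's own generators), and
each module turns them into one of the field's standard readouts. All
internal lengths are nanometres so that the three canonical thresholds stay
literal: 0.28 nm (first coordination shell), 0.5 nm (nonspecific contact),
3 nm (condensation layer).

## Contact statistic and the crystallographic reference scale

The coordination number *CN* counts protein–RNA non-hydrogen atom pairs
within *d*₀ = 0.5 nm. Two normalization decisions matter:

* **Residue normalization.** *CN*ₙ = *CN*/(*n*ₐₐ + *n*ₙₜ) makes complexes
  of different size comparable; the reference levels used in the trajectory
  annotations are 0.002 (the weakest crystallographic protein–RNA contact
  level), 0.02 (the protein–aptamer crystal reference) and 0.07 (the
  strongest).
* **Unit-cell expansion.** Crystal structures are only comparable after
  reconstructing the full unit cell: the asymmetric unit alone misses
  crystal contacts. `expand_unit_cell()` applies every symmetry operation
  (parsed from CRYST1/REMARK 290, with cartesian operators converted to
  fractional form), wraps images into the cell, and distances then use
  minimum-image periodic boundary conditions. The survey filter keeps
  entries with residue ratio *n*ₐₐ/*n*ₙₜ in [3, 15]; both bounds are
  inclusive, as are all distance thresholds (a pair exactly at *d*₀
  counts). Inclusivity is decided once and applied everywhere.

The switching function used for trajectory time series is a logistic
switch, *s(r) = 1/(1 + exp((r − d₀)/w))*, which recovers the sharp count
as *w* → 0 (asserted to 10⁻⁶ in the tests). The sharp Heaviside count is
the default because the survey usage reads as a plain pair count; the
smooth option exists for series where differentiability with respect to
geometry is wanted. The logistic form is this package's documented choice
of switching family, selected for its two-parameter simplicity and exact
sharp limit.

Frames without a box are treated with open boundaries: solution-phase
snapshots are analyzed per molecule, and wrapping them into an arbitrary
cell would create spurious image contacts.

## Ion shells and the half-split charge ledger

`classify_ions()` assigns every ion to exactly one class from its minimum
distance to each partner selection: `bridging` (within 0.28 nm of both),
`protein_only`/`rna_only` (within 0.28 nm of one), `condensed` (within
3 nm of the RNA), `bulk`. Three design choices:

* Shell membership uses the *minimum* distance to a selection, not per-atom
  contact multiplicity, because the bookkeeping counts ions, not contacts.
* The condensation layer is measured from the RNA by default (the diffuse
  layer forms around the polyanion); `shell_spec(condensation_from =
  "either")` widens it to both partners.
* A bridging ion is counted once as a bridge but appears in both partners'
  first-shell totals (`n1_protein`, `n1_rna`), which is the convention the
  charge ledger needs.

The ledger adds each exclusively adsorbed ion's full charge to its
partner's bare charge and splits bridging charges half-and-half. The split
conserves total charge exactly — an identity the test-suite checks on 1,000
random inventories — and the screening percentage, 100·|Qₐ(prot) +
Qₐ(RNA)|/|Q_bare|, is rounded to the nearest integer for reporting.

The 0.28 nm cutoff itself is calibratable: `calibrate_d0()` returns the
radius of the *first* interior maximum of an `rdf()` (first peak, not the
global one; a monotone g(r) falls back to the global maximum with a
warning). The RDF normalizes against the ideal-gas expectation in the
frame's cell; without a cell, the pair density is taken over the bounding
sphere of the selections — a stated convention rather than a physical
claim, adequate for peak location.

Windowed inventory statistics (mean ± sd per species and class) default to
one window per trajectory; for staged runs (e.g. stepwise Mg removal) the
window length in frames maps windows onto stages. A window longer than the
trajectory collapses to a single whole-trajectory window with a warning.

## Lennard-Jones complexation energy

`lj_complexation_energy()` evaluates the raw 12-6 cross sum with
Lorentz–Berthelot combining (arithmetic σ, geometric ε) and plain
truncation at 1.2 nm. Because only cross pairs enter, intramolecular and
1–4 exclusions are irrelevant by construction. Choices and degenerate
cases:

* The cutoff value is not dictated by the analysis it reproduces; 1.2 nm is
  a conventional biomolecular truncation radius and the tail error is
  bounded (a test asserts the analytic order-of-magnitude bound). Pass
  `cutoff = Inf` for the untruncated sum, `shift = TRUE` to zero the
  potential at the cutoff.
* Parameter lookup tries the atom name first, then the element symbol, and
  a missing class is a hard error naming the atoms — silent zero-parameter
  atoms would bias the sum.
* Exactly overlapping atoms (r = 0) are an error, not an infinity.
* The bundled `default_lj_table()` carries generic element-scale values for
  synthetic fixtures; production force-field parameters are user input via
  `read_lj_table()`, since redistributing a force field is outside this
  package's scope.

The energy time series flags frames below −50 kcal/mol (the level at which
wrapping becomes practically irreversible in the complexation analysis this
package supports) and −100 kcal/mol (deep wrapping).

## Structural metrics

RMSD solves the orthogonal Procrustes problem by SVD with reflections
excluded (determinant correction), mass-unweighted. SASA is a
Shrake–Rupley estimate with a deterministic golden-spiral lattice (default
960 points, probe 0.14 nm, built-in vdW radii for C/N/O/P/S/H/Na/Mg/Cl,
override by CSV); determinism was preferred over random sampling so that
reports are byte-reproducible. The single-sphere closed form is matched to
1 % at the default lattice.

The assembly extent is reported as *R* = Rg(union)/(Rg(protein) +
Rg(RNA)). The definition was an open design point; this form was chosen
because it is dimensionless, rigid-motion invariant, equals 0.5 for
coincident identical partners, exceeds 1 for well-separated ones, and
decreases monotonically as the protein envelops the RNA — matching the
qualitative direction (lower = tighter wrapping, with values near 0.9 for
moderate wrapping) that the readout needs. The `method` argument accepts a
replacement function so an alternative definition can be dropped in without
touching callers.

## The MC-RW generator

The builder prepares unbiased, non-overlapping starting configurations of a
disordered chain around a fixed partner — a geometry stage, not an
equilibrium sampler. Decisions:

* **Representation.** One backbone bead per residue (0.38 nm virtual bond,
  0.36 nm non-bonded clash radius). Excluded volume and contact detection
  are all this stage needs; heavy-atom decoration is a separate concern.
* **Anchoring.** The C-terminal bead is held fixed; the default six walks
  fan their anchors around the partner's centre so samples differ by
  anchor pose, while the rest of the chain explores freely.
* **Move set.** Pivot rotations about a random backbone bead (free-end
  segment) plus short crankshaft rotations of interior blocks — a standard
  ergodic pair for excluded-volume chains; both conserve bond lengths
  exactly (asserted to 10⁻⁹).
* **Random temperature.** Per step, the Metropolis temperature is drawn
  log-uniformly from a configured range; with a fixed schedule the walk is
  plain Metropolis, and with the default hard-sphere energy every
  non-clashing move is accepted at any temperature (asserted: zero
  Metropolis rejections). The log-uniform law is this package's concrete
  reading of "random temperature"; it is configurable and recorded in the
  output manifest.
* **Stopping.** Each walk returns its *first* configuration with ≥ 1
  non-hydrogen cross pair within 0.5 nm — the same *d*₀ as the nonspecific
  contact statistic — and zero clashes. A walk that exhausts `max_steps`
  reports failure without hiding the other samples.

## Synthetic data: what it emulates and what it does not

The generators produce desk-scale analogues of the study system: a hairpin
polyanion with two OP oxygens per phosphate and no 5′ phosphate (so a
40-mer carries −39); a polyampholyte whose default placement law puts 30
acidic and 4 basic residues in the first 100 positions (first-100 charge
−26, total −44); ion clouds with planted shell assignments; trajectories
with prescribed contact or occupancy time courses; and toy crystal sets
with exactly known cross-pair counts, including a protein–aptamer analog
planted at *CN*ₙ = 12/600 = 0.02 and a 26-of-41 ratio-filter yield.

Planting is verified in a closed loop: `plant_ions()` re-classifies its own
output and refuses geometries it cannot realize. Coordinate noise is
independent Gaussian jitter with stated σ, small enough (margins of at
least 4σ around every threshold) that planted counts are exact, not
approximate.

What passing these tests shows: the analysis operators implement their
definitions correctly (counts, shells, ledgers, energies, metrics agree
with brute-force oracles and closed forms). What it does not show: fidelity
to real solvated systems. The fixtures have no water, no base atoms, no
force-field dynamics, and ion placements are geometric rather than
Boltzmann-weighted; conclusions about real trajectories require real
trajectories.

Problem sizes are chosen for seconds-scale runs: fixtures of a few hundred
to a few thousand atoms, trajectories of 4–16 frames, survey sets of ≤ 41
entries, MC-RW chains of 20–30 beads. Every generator is deterministic
given its seed.

## Degenerate inputs and error policy

Empty selections are returned with a warning (an empty selection is a
legitimate query result) but analyses that *require* atoms on both sides —
coordination numbers, ledgers with two partners — raise errors.
Single-partner ion classification is allowed: distances to an absent
partner are infinite, which yields the free-polyanion shell analysis.
Malformed structure records error with the offending line number; unknown
residues are kept, tagged `other`, excluded from partner selections, and
reported once per file. Empty trajectories produce empty reports with a
warning rather than failing a pipeline.

## Known limitations

* The crystallographic reference comparisons need user-supplied coordinate
  files; the package ships no PDB entries.
* The minimum-image convention uses the nearest-lattice-point
  approximation, exact for orthorhombic cells and standard for mildly
  skewed ones; extremely oblique cells would need an image scan.
* SASA treats the selection as both surface and occluder set; occlusion by
  atoms outside the selection is not considered.
* The MC-RW stage has no attractive energetics, so its ensembles are
  uniform over excluded-volume-allowed first-contact geometries, not
  thermodynamic ensembles.
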