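---
title: "Methods: endpoint energetics and dynamics analysis in mdsie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endpoint energetics and dynamics analysis in mdsie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mdsie` is a desk-scale re-implementation of the standard post-simulation
analysis stack for protein–ligand complexes: solvated interaction energy
(SIE) endpoint binding free energies, dynamic cross-correlation and
fluctuation analysis, empirical hydrogen-bond and screened-Coulomb
per-residue energetics, hydrophobic-contact profiling, and computational
alanine scanning. The motivating application is inhibitor binding to the
adipocyte fatty-acid binding protein (A-FABP), where a carboxylate-bearing
inhibitor salt-bridges a C-terminal arginine (R126 in the usual numbering)
and the question is how much each interaction type contributes and what
binding does to the protein's internal motions. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish.

## The SIE model

The binding free energy of a bound snapshot ensemble is estimated as

$$\Delta G_{bind} = \alpha\,\bigl[E_C(D_{in}) + E_{vdW} +
\Delta G^R(D_{in},\rho) + \gamma\,\Delta MSA(\rho)\bigr] + C$$

with the published global calibration
`alpha = 0.104758`, `D_in = 2.25`, `rho = 1.1`,
`gamma = 0.012894` kcal·mol⁻¹·Å⁻², `C = -2.89` kcal·mol⁻¹
(`sie_coefficients()`). The four components are:

* `E_C`: intermolecular Coulomb energy between protein and ligand, with
  the constant 332.0637 kcal·mol⁻¹·Å·e⁻² and the interior dielectric
  `D_in`. No distance cutoff — cutoffs belong to simulation engines, not to
  post-analysis.
* `E_vdW`: 12-6 Lennard-Jones energy in the `rmin/2`–`epsilon` convention
  with Lorentz–Berthelot combination.
* `ΔG^R`: change in reaction-field (electrostatic solvation) energy on
  binding, `RF(complex) − RF(protein) − RF(ligand)`, from a two-dielectric
  Poisson solve with radii scaled by `rho`. For a charged ligand binding
  into a pocket this is a positive desolvation penalty.
* `γ·ΔMSA`: molecular-surface-area change scaled by `gamma`; burying
  surface on binding makes it negative.

Component means over snapshots are reported ± the standard error of the
mean (no block averaging; snapshots 100 ps apart in the motivating use
case are treated as independent). `ΔG_bind` is computed from the component
means, and the container enforces that identity to 1e-9. All three group
energies are evaluated on the same complex trajectory (single-trajectory
approximation); computing mutant energies on wild-type snapshots
(`mutate_trajectory()`) is the same approximation one level up, and is
documented as such wherever it is used.

Feeding published component tables for the three A-FABP inhibitors (8CA,
F8A, I4A; transcribed under `inst/extdata/`) through `sie_from_table()`
reproduces their reported `ΔG_bind` values within 0.05 kcal·mol⁻¹, the
slack expected from components printed to two decimals.

## The finite-difference reaction field

The reference implementations of SIE use a boundary-element Poisson
solver that is not freely available. `mdsie` substitutes a
finite-difference solver (C++/Rcpp):

* node-centred potential on a cubic grid, default spacing 0.5 Å, 10 Å
  solvent margin; solvent dielectric 78.4;
* trilinear charge spreading; edge dielectrics from the fraction of each
  edge inside the scaled van der Waals surface, averaged harmonically
  (5 samples per edge);
* Dirichlet boundaries from the Coulomb potential in the outer
  dielectric; successive over-relaxation until the largest potential
  update falls below 1e-4 kcal·mol⁻¹·e⁻¹;
* the reaction energy is `0.5 Σ q_i (φ_het − φ_hom)` where the
  homogeneous solve uses the interior dielectric everywhere. Using the
  same grid and the same spread charges makes the grid self-energy cancel
  exactly.

Two numerical details matter. First, the union-of-spheres boundary is
jagged on a grid, and the jaggedness depends on where the grid origin
happens to fall; the solver therefore averages a small number of
fractional origin shifts (`n_offsets`, default 2), which removes most of
this grid-phase noise at linear cost. Second, accuracy is validated
against closed forms rather than against another solver: the Born ion
across radii 1.5–4 Å agrees within 3% (typically under 2%), and halving
the grid spacing on the toy complex moves the reaction energy by under
2%. Those two checks — plus exact quadratic charge scaling, which holds
because the solver is linear — are the acceptance basis for this module.

## Surface areas

`sasa()` is a plain Shrake–Rupley implementation: each atom's sphere
(radius `vdw·scale + probe`) is sampled with a deterministic golden-spiral
quadrature (default 960 points) and points buried in any neighbour sphere
are discarded. It is validated against the analytic sphere (0.5%) and the
analytic two-overlapping-spheres outer surface (1%). The SIE surface term
uses the scaled-radius surface as the molecular-surface proxy; the probe
radius is configurable and the γ·ΔMSA sign structure (negative on any
bound pose) is what the downstream arithmetic relies on.

## Dynamics: superposition, RMSF, DCCM

Superposition is closed-form least squares (Kabsch via SVD, with the
determinant correction so only proper rotations are returned). RMSF and
the cross-correlation matrix use frames superposed onto an iterated mean
structure (superpose to frame 1, average, superpose to the mean, average
again) — standard practice when no reference is stated. The DCCM is

$$c_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{\sqrt{\langle \Delta r_i^2\rangle\,\langle \Delta r_j^2\rangle}}$$

over selected Cα atoms; entries lie in [−1, 1] with unit diagonal, and
zero-variance atoms get zeroed rows/columns with a warning instead of
NaNs. Analyses default to the trailing third of frames
(`equilibrium_frames()`), the analogue of analysing the last 20 ns of a
60 ns run; the fraction is a config knob. Region summaries take named
inclusive residue ranges in author numbering (e.g. the C-terminal
β-strand block 122–131 in the A-FABP application) and report per-region
means and signed bound-vs-unbound differences.

One subtlety is worth stating because it shapes the synthetic tests:
least-squares superposition removes the net rigid component of whatever
motion the fit atoms share. If the fit set itself carries the correlated
motion being measured, part of that motion is projected out and the DCCM
underestimates it — with a 9-residue toy and a 6-residue planted block
the planted 0.8 would drop to about 0.33. This is a property of the
method, not a bug; the practical remedy, here as with real proteins, is
to superpose on a quiet core.

## Hydrogen bonds and polar interactions

Detection is geometric, per frame: donor–acceptor distance ≤ 3.5 Å and
donor–H⋯acceptor angle (at the hydrogen) ≥ 120°, reported when satisfied
in ≥ 50% of frames. All three criteria are knobs, since no single
convention is universal. Donors are N/O/S atoms with a hydrogen within
1.25 Å; structures without hydrogens are refused with an explicit error
(protonation assignment is out of scope). Distance distributions use
0.05 Å bins, frequencies sum to one, and the reported peak is the modal
bin centre.

Per-bond energies use a two-parameter empirical well in the H⋯acceptor
distance with the calibrated constants 5.571 and 668.580:

$$E_{HB}(d) = \frac{668.580}{d^{12}} - \frac{5.571}{d^{2}}$$

whose minimum (−1.25 kcal·mol⁻¹ at 1.93 Å) sits inside the 1.8–2.6 Å
band where strong protein–ligand hydrogen-bond distance distributions
peak, and which decays to zero at separation. Both exponents are
configurable in `hbond_energy_model()`. Published per-bond means cannot
be reproduced exactly from peak positions alone — they are trajectory
averages over distributions whose widths are not tabulated — so the
package asserts oracle equality, sign and shape properties for this
operation, and uses plain summation (`complex_hbond_total()`) for the
reported per-complex totals, which is exact.

Per-residue polar interactions are screened Coulomb sums,

$$E = s \sum_{i \in res}\sum_{j \in lig}
\frac{332.0637\,q_i q_j}{\varepsilon(r_{ij})\, r_{ij}}$$

with the sigmoidal distance-dependent dielectric in the Mehler–Solmajer
parameterisation as distributed with AutoDock 3.0.5
(`A = −8.5525`, `k = 7.7839`, `λ = 0.003627`, `ε₀ = 78.4`) and the
calibrated scale `s = 1.558`. The dielectric is monotone non-decreasing
and approaches the solvent value at large distance; both properties are
tested over r ∈ [0.1, 50] Å.

Hydrophobic contacts follow the classic LIGPLOT-style rule: a residue is
in contact in a frame when any of its carbon/sulfur heavy atoms is within
3.9 Å (configurable) of a ligand carbon/sulfur atom; per-residue
occupancies over frames are reported.

## Alanine scanning

`mutate_to_alanine()` truncates the target side chain at Cγ: atoms beyond
Cβ are removed, the Cγ atom is replaced by a hydrogen (HB1) at 1.09 Å
along the former Cβ→Cγ direction, the residue is renamed ALA and
re-parameterised from the table's ALA rows. Glycine/alanine targets and
residues lacking Cβ/Cγ are refused with the system unchanged. Nothing
outside the target residue is touched (asserted bitwise in the tests).
`mutate_trajectory()` applies the same truncation frame-wise so mutant
energies can be rescored on the wild-type ensemble; a user-supplied
mutant trajectory can be used instead when available. ΔΔG =
ΔG(mutant) − ΔG(wild), positive for destabilising mutations; when an
externally reported ΔΔG is supplied it is cross-checked against the dG
columns and flagged on disagreement rather than echoed (the transcribed
I4A table row is exactly such a case: its reported 2.18 contradicts its
own columns, which give 1.68).

## The synthetic world

The generator exists so every stage has an input with known ground truth:

* **Toy complex** (`build_toy_complex()`): a 9-residue peptide arc
  (ALA-SER-ALA-LEU-ALA-TYR-ALA-ARG-ALA, chain A) around a benzoate-like
  ligand (net −1). Planted exactly: a bidentate arginine salt bridge
  (HH21⋯O1 1.86 Å, HE⋯O2 1.95 Å, collinear at the hydrogen), a tyrosine
  hydroxyl donating to O2 (1.85 Å), a ligand hydroxyl donating to the
  serine OG (1.9 Å), and a leucine isopropyl cap 3.3–3.6 Å above the
  ring. Charges are schematic but integral per residue (ARG +1, ligand
  −1, rest 0). The geometry away from these planted features —
  backbone bond lengths, ring regularity — is deliberately approximate:
  none of the analyses consume it. At 80 atoms the Poisson solve runs in
  seconds.
* **Fluctuation trajectories** (`gaussian_trajectory()`): residues move
  as rigid units with isotropic Gaussian displacements; residues inside a
  planted correlation block share pairwise correlation c (default 0.8,
  coupling the two termini, the analogue of the terminus coupling that
  inhibitor binding switches off) and fluctuate with σ = 0.4 Å per axis;
  scaffold residues and the ligand fluctuate with σ = 0.02 Å. The quiet
  scaffold is the idealisation that makes exact recovery possible: the
  superposition fit set must not share the planted motion (see above).
  Real protein cores fluctuate more, so a green recovery test
  demonstrates estimator correctness, not robustness to fit-set
  contamination. Per-frame rigid-body noise (0.1 Å translations, ~1°
  rotations) is added on top so the superposition path is genuinely
  exercised.
* **Hydrogen-bond trajectories** (`planted_hbond_trajectory()`): the
  ligand translates rigidly along the monitored H⋯acceptor axis so the
  distance series follows the requested Gaussian mixture exactly
  (default single peak at 1.81 Å, σ = 0.1 Å, matching a strong narrow
  salt-bridge bond).

All generators are bitwise deterministic under `seed`
(Mersenne-Twister/inversion, fixed explicitly).

What the green suite establishes: the estimators recover planted
correlations to ±0.02 at 20 000 frames, planted σ to 2% at 50 000
frames, and planted distance peaks to one histogram bin; the energy
kernels agree with independent brute-force oracles to 1e-10 and with
closed forms at stated tolerances. What it does not establish: force-field
realism, conformational sampling quality, or the accuracy of the
single-trajectory approximation for mutants — those depend on the
simulation data fed in, which is out of scope here.

## Degenerate inputs and tie-breaks

* Alternate locations: highest occupancy wins, ties keep the first
  encountered, and the choice is logged.
* Overlapping atoms (r < 0.1 Å) abort energy evaluations with the pair
  named.
* Collinear or sub-3-atom superposition selections are refused.
* Zero-variance atoms in the DCCM give zeroed rows/columns plus a
  warning.
* Missing parameter-table entries are a hard error listing the atoms; no
  silent defaults.
* Per-residue summed charges must be within 0.01 e of an integer after
  assignment.

## Known limitations

* The hydrogen-bond well is a surrogate form around published constants
  (see above); totals and comparisons are unaffected, absolute per-bond
  strengths should be read qualitatively.
* The FD Poisson solver is validated against closed forms and
  self-convergence, not against boundary-element references.
* Trajectories are multi-model PDB only; the reader contract
  (`read_trajectory(path, system)` returning an F × N × 3 `trajectory`)
  is the single seam where binary formats could be added without touching
  analysis code.
* The CLI is deliberately thin; orchestration beyond the provided stages
  belongs in user scripts.
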