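---
title: "Structure-based coarse-graining by Iterative Boltzmann Inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based coarse-graining by Iterative Boltzmann Inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibicg)
```

## The problem and the method

A coarse-grained (CG) model replaces groups of atoms by single beads so
that systems far beyond all-atom reach — adsorption of peptides and
proteins on carbon nanotubes is the motivating case here — can be
simulated. The structural route to a CG force field asks: *which pair
potential makes the CG simulation reproduce a chosen target
distribution?* By Henderson's theorem the pair potential reproducing a
given radial distribution function g(r) at a fixed state point is unique
up to an additive constant, so matching g(r) is a well-posed inverse
problem.

The zeroth-order answer is the potential of mean force (PMF),

U⁰(r) = −k_B T ln g_target(r),

which is exact only at infinite dilution. Iterative Boltzmann Inversion
(IBI) repairs it by a fixed-point iteration: simulate with the current
table U_n, measure g_n, and update

U_{n+1}(r) = U_n(r) + k_B T ln [ g_n(r) / g_target(r) ] + ΔU(r),

where ΔU(r) = α (1 − r/r_cut), α = −0.001 k_B T, is a small linear tail
correction applied every update (it regularizes the long-range tail and
is the conventional hook for pressure corrections). Iteration quality is
scored by the weighted functional

f_target = ∫ e^{−r} (g(r) − g_target(r))² dr   (r in nm),

whose weight emphasizes the physically decisive short-range structure.
Bond-length and angle distributions are inverted once
(U = −k_B T ln P, no Jacobian factors — the tables state this in their
headers so files are self-describing) and never iterated; only the
non-bonded table of one designated type pair is refined.

Everything runs in GROMACS units (nm, ps, amu, kJ/mol, K;
k_B = 0.0083144621 kJ/(mol K)); β = 1/(k_B T) is always derived from
these constants.

## Mapping

Beads sit at the center of mass of their atom groups and carry the
summed mass. Groups are made whole across the periodic boundary
(minimum-image unwrap relative to the group's first atom) before the COM
is taken, because the raw COM of a boundary-straddling group is
meaningless. The two reference schemes are:

* **CNT**: atoms sorted along the tube axis, grouped ten per bead. The
  (5,5) armchair tube spanning a 2.93 nm periodic cell has 240 atoms and
  maps to 24 beads — one per atomic ring, so the bead chain is evenly
  spaced.
* **Capped amino acid**: three beads — acetyl cap (ACE), the whole
  residue including its side chain (AA), amine cap (NH2). Cap atoms are
  excluded from the AA bead (the alternative, folding caps into the
  residue bead, would double-count mass across beads and is not used).

Solvent is excluded entirely: the CG model is implicit-solvent, its
potentials are solution-averaged free energies.

The tube generator derives the (n,n) cell length √3·c_cc from the C–C
bond (0.142 nm gives 0.24595 nm). A requested box within 0.1 cells of an
integer multiple is accepted and the tube is uniformly strained to span
it exactly (the standard construction for periodic tubes; the reference
2.93 nm box is 11.91 cells and becomes 12 strained cells); anything
further off is rejected as non-commensurate.

## Distributions

`radial_distribution()` histograms minimum-image pair distances between
two type sets and normalizes by the homogeneous ideal-gas shell count
N_a ρ_b 4πr² dr. For the tube–amino-acid pair the geometry is
anisotropic, but the estimator is deliberately frozen as part of the
file contract: the IBI fixed point only requires that target and
iterate use the *identical* estimator, and the conventional form keeps
the tables comparable with standard tools. Bins are left-edged with
values at bin midpoints; defaults are dx = 0.01 nm for r and 1° for θ
(declared choices — not inferred from any reference data). Bond and
angle histograms are normalized to unit trapezoidal integral. Boxes are
orthorhombic throughout, minimum image by nearest-integer division per
axis.

## Inversion and tabulated potentials

`pmf_from_rdf()` inverts g where g > g_floor (10⁻⁶; bins at or below it
count as unsampled). The unsampled core is filled by linearly
extrapolating the innermost sampled slope, which always yields a
repulsive wall (a degenerate non-negative inner slope falls back to a
steep default wall of 100 k_B T/nm so the invariant survives pathological
inputs). Interior gaps are bridged linearly. Non-bonded tables are
truncated and shifted to zero at r_cut (1 nm, the reference van der
Waals cutoff); bond/angle tables are min-shifted instead.

Force columns are built by central differences (one-sided at the edges)
and zeroed at and beyond the cutoff, and are stored alongside U in
GROMACS-style three-column text. One deliberate deviation: the
literature formula differentiates ln g_n for the iterated force, which
for n ≥ 1 is not the derivative of the accumulated U_n; this package
differentiates the accumulated potential, the physically consistent
choice (for n = 0 the two coincide exactly).

## The CG engine

Leapfrog integration (dt default 0.001 ps) with all-pairs tabulated
non-bonded forces under a cutoff, tabulated bonds and angles, per-step
removal of the mobile subsystem's center-of-mass motion, and a choice of
thermostats. "V-rescale" is implemented as the canonical stochastic
velocity-rescaling scheme (CSVR): the kinetic energy is propagated with
the exact canonical kinetic-energy distribution as its stationary law,
with coupling time τ_T. A Berendsen thermostat is included for parity;
`thermostat = "none"` gives NVE. All stochastic draws go through R's
RNG, so runs are bit-reproducible given the seed.

Within a table segment the force is interpolated linearly and the
energy is evaluated as the exact anti-derivative of that interpolated
force anchored at the left node. This makes the reported energy exactly
consistent with the applied force everywhere (numerical gradients of the
energy match the forces to float precision), at the cost of an O(dx³)
node mismatch relative to the tabulated U values — far below the
interpolation error of the tables themselves. Distances below a table's
range continue its repulsive wall linearly and are counted
(`clamped`); distances beyond the last node continue with the edge
slope. Degrees are the angle-table unit; the engine converts the
tabulated derivative to per-radian generalized forces internally.

Practical integration limits are system-dependent: the stiff tube-chain
bonds (period ≈ 0.24 ps in the toy parameterization) demand dt well
below that period, while a bead fluid with only soft non-bonded tables
tolerates far larger steps. The engine detects blow-ups and reports the
offending step and bead rather than asserting any universal stability
ceiling.

Temperature is T = Σ m v² / (N_df k_B) with N_df = 3 N_mobile − 3 (COM
motion removed). Frozen beads accumulate force but never move and do not
count toward N_df.

## The IBI loop

`run_ibi()` is the package's fitting function. Per iteration n it seeds
the engine with base_seed + n (recorded, so any archive replays bit for
bit), simulates, discards the first 20% of sampled frames as
equilibration, measures g_n, scores f_target, and stops at f_tol or the
iteration cap (default 100). The returned `ibi_fit` reports the *best*
iteration, not the last. Update details:

* **Damping** (default 0.2) multiplies the ln-ratio increment. It
  changes the path, never the fixed point; undamped IBI with noisy RDFs
  oscillates.
* **Unsampled bins**: where only one of g_n, g_target is sampled the
  increment is capped at ±2 k_B T per iteration, preventing runaway
  walls.
* **Smoothing** is applied to the *increment*, not the accumulated
  potential, so an exact target match leaves U_n unchanged — the fixed
  point is preserved to machine precision. The default is a 5-point
  moving average. Note a real limitation of short moving-average
  filters: a 3-point MA has a spectral null at wavelength 3 bins, so
  corrections with structure at that scale can never be accumulated and
  the iteration floors early. Where the measured RDFs are already
  low-noise (the closure runs below), smoothing is best disabled
  (`smooth_window = 1`).
* **ΔU** is added unconditionally by default, matching the update
  equation; a switch disables it for fixed-point tests.
* Only the designated `iterate_pair` table is refined; every other
  non-bonded, bond and angle table stays at its Boltzmann-inverted (or
  ground-truth) value.

## Closure fixtures: what is emulated, and what is not

No all-atom reference ensembles ship with the package; targets come from
the package's own engine under a *known* potential ("closure" or
self-consistency fixtures). This tests the whole inverse loop — if the
method works, starting from the PMF of a target generated under a known
table must drive f_target to the noise floor and recover that table up
to an additive constant within noise. It does not test force-field
quality against chemistry: toy residue geometries are mass-correct but
shape-coarse, and a passing closure run says nothing about how well a
CG model reproduces real all-atom ensembles of solvated systems.

Two presets:

* **fluid** — 160 LJ beads (σ = 0.34 nm, ε = 1.5 kJ/mol, m = 72 amu) in
  a 2.2³ nm³ box at 330 K: reduced density ρσ³ ≈ 0.59, reduced
  temperature k_BT/ε ≈ 1.83. The state point is deliberately
  supercritical and dense: near or below the LJ critical temperature
  (T* ≈ 1.31) the fluid phase-separates and its RDF becomes
  irreproducible between runs, which no inverse method can fix. Many
  beads give ~12,700 pairs, so a 50,000-step iteration measures g with
  per-bin noise of a few tenths of a percent and the f_target noise
  floor sits near 3×10⁻⁵ — safely below the 10⁻⁴ tolerance. This is the
  preset used for convergence checks.
* **cnt-peptide** — the 24-bead tube chain (harmonic-table bonds and
  angles, periodic along z) plus one mobile ACE–AA–NH2 peptide in the
  reference 4.16 × 4.16 × 2.93 nm box, iterated pair AA–CNT. With a
  single peptide there are only 24 iterated pairs per frame, so the RDF
  noise floor at desk-scale run lengths exceeds 10⁻⁴; this preset is
  therefore used for protocol checks (thermostat fidelity, bonded
  distribution extraction), not for convergence-to-tolerance runs.

The ground-truth table is a truncated-shifted 12-6 with its core
linearized above 150 kJ/mol (a definite, finite tabulated potential —
the recovery test compares against the table, not the analytic form).
Thermostat-fidelity runs use τ_T = 0.05 ps: tight coupling maximizes the
number of independent kinetic-energy samples a fixed 100,000-step run
yields, which is what a variance check needs; dynamical properties are
not measured in those runs, so the aggressive coupling costs nothing.

Problem sizes throughout the test suite (160-bead fluid, 150,000-step
targets, 50,000-step iterations, 64-bead NVE checks) were chosen so the
f_target noise floor and statistical test powers work out as computed
above; they are the package's declared desk-scale study conditions.

## Known limitations

* All-pairs force loop: fine for the reference systems (≤ a few hundred
  beads); no cell lists.
* Orthorhombic boxes, no electrostatics, no pressure coupling, no
  constraints — matching the scope of the CG model.
* The RDF normalization is the homogeneous convention even for the
  anisotropic tube geometry (see above; frozen by contract).
* IBI refines a single pair table per run.
* Closure fixtures validate the inverse machinery, not chemical
  realism.
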