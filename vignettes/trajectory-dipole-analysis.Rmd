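---
title: "Shape, dipole and field-response analysis of protein trajectories"
author: "tubupol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape, dipole and field-response analysis of protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubupol)
```

## The problem

An intense (MV/m-scale) nanosecond electric pulse interacts with a protein
through its charge and dipole moment. The αβ-tubulin heterodimer is an
extreme case: with its two acidic C-terminal tails (CTTs; the last 16
residues of the α chain, `GVDSVEGEGEEEGEEY`, and the last 20 of the β
chain, `QDATADEQGEFEEEGEEDEA`) it carries a structural charge around
−33 e and a dipole of thousands of debye, so the coupling energy μ·E
exceeds thermal energy k~B~T already below 1 MV/m (for 2,166 D at 300 K
the crossing is near 0.57 MV/m). The analytical difficulty is that a field
acts on such a protein in two ways at once: it rotates the whole molecule
(torque on the dipole) and it polarizes it internally (most visibly by
pulling the charged tails outward). Raw lab-frame dipole series mix the
two effects inseparably.

This package implements the standard remedy — a body-fixed coordinate
frame built from the positional covariance of the atom cloud — together
with everything needed around it: structure and charge I/O, dipole
computation under explicit conventions, trajectory statistics, per-residue
and binding-site shift maps, a microtubule-lattice energy model, and a
synthetic trajectory generator with exact ground truth.

## The covariance-ellipsoid frame

For the `N` selected atoms of one frame,

$$\tilde C = \frac{1}{N} \sum_{l=1}^{N} (\mathbf r_l - \langle \mathbf r\rangle)
  (\mathbf r_l - \langle \mathbf r\rangle)^T ,$$

an unweighted 3×3 positional covariance (nm²). Its eigenvectors are the
axes of the ellipsoid best fitting the cloud; eigenvalues are the mean
square fluctuations along them. We order eigenvalues ascending and name
the axes x′ = minor, y′ = medium, z′ = major. A vector expressed in this
frame (`to_internal()`) is invariant under any rigid rotation or
translation applied to the whole system — the property that makes internal
dipole components read as genuine polarization. The suite verifies this
directly: on a rigidly tumbling synthetic trajectory the lab dipole swings
by hundreds of debye while the internal components stay constant to below
10⁻⁶ D.

Numerical choices, all deliberate:

* **Sign continuity.** Eigenvector signs are arbitrary per frame, so each
  eigenvector is flipped to maximize its dot product with the previous
  frame's. The first frame anchors signs by positive dot products with the
  lab x, y, z axes (ties broken toward +z), making runs bit-reproducible.
* **Handedness.** If the resulting determinant is −1 the minor axis is
  flipped, so the frame is always right-handed.
* **Degeneracy.** Eigenvalue gaps below 10⁻⁶ nm² make the frame
  ill-conditioned; without a previous frame this warns and falls back to
  the deterministic (but arbitrary within the degenerate subspace)
  eigen-solver output. Clouds with fewer than 4 points or rank-deficient
  geometry are rejected.
* **Atom selection.** All protein atoms, unweighted, matching the
  covariance definition above; waters and ions are never part of a
  `structure_model`.

**Axis lengths.** The eigenvalue-to-length mapping is a convention, not a
fact: for points uniformly filling a solid ellipsoid the semi-axis is
√(5λ); for a uniform shell it is √(3λ). We default to the solid-body
mapping (`"uniform-solid"`) because a globular protein is closer to a
filled than a hollow body, implement `"uniform-solid-full"` (2√(5λ)) and
`"shell"` as alternatives, and stamp the convention onto every output so
that calibration against independently produced reference trajectories can
select a different one without ambiguity. Reported absolute dimensions
should never be compared across conventions.

## Dipole conventions

`dipole_moment()` computes μ = Σ qᵢ(rᵢ − O) and converts e·nm → debye with
the fixed constant 48.0321 D/(e·nm) (CODATA-derived; hard-coded so outputs
are bit-stable). Key decisions:

* **Origin.** For net-charged selections μ depends on O. The default is
  the selection's center of mass (element masses from a small internal
  table; pseudo-atoms weigh as carbon), the common force-field-tool
  convention; `"cog"` and `"fixed"` are available, and the mode is
  recorded on every result. Absolute dipole magnitudes from differently
  documented origins are not comparable — which is why the package
  promises convention-stable computation rather than reproduction of any
  particular absolute value.
* **Per-residue dipoles** are taken about each residue's own center of
  mass. This makes charged-residue dipoles well-defined and invariant
  under translation of the whole structure, and it is the right scale for
  shift maps: differences of a few debye per residue would be swamped by
  any global-origin bookkeeping. They require per-atom (partial) charges;
  a residue collapsed to one formal point charge has no internal dipole.
* **Formal charges** at pH 7: Asp/Glu −1, Lys/Arg +1, His neutral
  (configurable — force-field defaults at pH 7 commonly deprotonate
  histidine's second nitrogen), everything else 0. Terminal ±1 charges are
  off by default because the main use is sub-chain selections (tails,
  sites) that have no free termini; for whole chains they can be enabled.
  The β-CTT sequence above totals −11 e, the α-CTT −8 e, which is roughly
  a third of the −33 e protein — the quantitative reason the tails
  dominate the field response.

## Trajectory statistics

* **Segment statistics** (`segment_stats()`): the last 5 ns are tiled by
  5 segments of 1 ns; the reported value is the mean of segment means and
  the uncertainty is the *sample SD across the 5 segment means* (the
  per-frame SD is emitted alongside for transparency, since the two are
  easily conflated).
* **Histogram sampling** (`last_window_samples()`): exactly
  window/stride samples (250 at the 5 ns / 20 ps defaults), strided to end
  at the final frame.
* **Dipolar shift maps** (`residue_dipole_shift()`): per residue, mean
  internal y′ dipole over the last window of the exposed run minus the
  reference run; `count_exceeding()` tallies residues beyond a ±5 D
  threshold per chain. The operation is antisymmetric in its two
  arguments, which the suite asserts.
* **Coil counts**: secondary-structure assignment is consumed, never
  computed — a per-frame DSSP-style label table is an input contract.
  Smoothing is a centered moving average (width in frames, caller's
  choice) because published smoothed representations rarely state their
  parameters; raw counts are always returned.
* **PBC guard**: frames are assumed whole-molecule; inter-frame atom jumps
  above 3 nm trigger a wrapping-artifact warning rather than silent
  nonsense.
* **Gapless numbering**: crystallographic tubulin entries contain gaps
  (2 missing residues after β-44, 8 after β-360 in the gapped originals);
  `renumber_gapless()` renumbers each chain consecutively *from its first
  author number*, so a chain fragment starting at 43 stays anchored at 43
  while the successor of 360 becomes 361. The old→new map is retained and
  exportable.

## The lattice energy model

The microtubule-lattice balance treats the inter-dimer dipole-dipole
energy as the only dipole-dependent term: E_dd(μ) = E_ref·(μ/μ_ref)², with
the reference calibration E_ref = 27 kcal/mol at μ_ref = 4,500 D and net
free energy G_ref = −9 kcal/mol there. All other contributions (surface
area, van der Waals, generalized-Born electrostatics) are lumped into the
μ-independent baseline B = G_ref − E_ref = −36 kcal/mol, exactly as the
reference arithmetic implies; the package applies that arithmetic without
further interpretation (per-dimer versus per-lattice scaling of E_ref is
not resolved by it). G(μ) = B + E_dd(μ) then classifies the lattice stable
(G < 0) or unstable, with the closed-form threshold
μ\* = μ_ref·√(−B/E_ref) ≈ 5,196 D at the defaults.

## The synthetic generator

`synthetic_spec()` / `make_ellipsoid_protein()` / `simulate_trajectory()`
produce trajectories whose every relevant property is known in closed
form. The defaults are the emulated study conditions, chosen once:
semi-axes (2.28, 2.65, 4.85) nm (zero-field tubulin ellipsoid); 2,000 body
atoms in 10-atom pseudo-residues (a deliberately scaled-down stand-in for
the ~14,000-atom dimer — large enough that sample-covariance noise is
negligible, small enough that the full 30 ns × 20 ps pipeline runs in
seconds); body point charges summing with the tail to −33 e and giving a
multi-thousand-debye dipole; the β-CTT sequence as the 20-residue tail
(−11 e); a 100 MV/m field along lab z for 30 ns; rotational diffusion
0.02 rad²/ns (Stokes-scale for a ~5 nm protein in water at 300 K); tail
relaxation 1 ns.

Mechanics per 20 ps step:

1. **Rotation**: overdamped Langevin update, dθ = (μ×E)·(D_r/k_BT)·dt plus
   isotropic Gaussian noise of variance 2·D_r·dt per axis; steps above
   0.5 rad abort as a timestep error. The torque dipole is recomputed from
   the current coordinates about the center of mass each step.
2. **Tail stretch**: a scalar s relaxing toward the saturating equilibrium
   s_eq(E) = A·E/(E + E₀) (E₀ = 25 MV/m) with first-order kinetics,
   integrated exactly over the step. The saturating form gives
   proportional response at low field and a plateau at high field —
   qualitatively the observed behaviour — with no claim of physical
   fidelity; A and E₀ are free knobs.
3. **Optional uniform drift** of the center.

Two constructions make the ground truth *exact* rather than approximate.
The tail is attached along the **sample** medium-axis eigenvector of the
generated body cloud, and atom i is displaced by s·(i/n) along that same
axis. Displacements collinear with an eigenvector perturb the covariance
only on its own diagonal, so the frame axes are unchanged by any stretch,
and the imposed internal y′ dipole change is exactly k·s with
k = 48.0321·(Σqᵢwᵢ − Q·w̄) D/nm computed from the tail charge pattern.
By default A is calibrated so |k·s_eq| = 40 D at 100 MV/m — the emulated
tail-polarization magnitude. Second, because every other motion is rigid,
the internal-frame transform removes it identically; the pipeline's
measured last-window shift therefore matches the imposed value to well
inside the 5 % acceptance tolerance, and the residual is integration
convergence of s, not estimator noise.

**What passing tests do and do not show.** The generator validates the
*analysis machinery*: frame continuity, origin conventions, unit handling,
window statistics, parameter recovery. It has no force field, no solvent,
no thermostat, no conformational flexibility beyond the one tail
coordinate, and its tail has no secondary structure to lose — so passing
tests say nothing about whether a real protein polarizes by 40 D, only
that if it did, this pipeline would measure it correctly. Coil-count
analysis is exercised with constructed label tables for the same reason.

Every output records its seed; `write_fixtures()` emits PDB + multi-frame
XYZ (nm, with `time_ps=` tags) + charge CSV + ground-truth JSON. XYZ is
used for fixtures because it is plain text; binary trajectory formats are
out of scope for the generator.

## Problem sizes and runtime

The shipped tests run the full study-condition pipeline once (2,024 atoms,
1,501 frames, exposed + reference) plus many smaller constructions
(400-atom bodies, 2–8 ns runs); the whole suite completes in well under a
minute on one CPU. Monte-Carlo axis recovery uses 10⁵ samples, where the
√(5λ) mapping recovers (1, 2, 3) nm semi-axes within 1 %.

## Known limitations

* Absolute dipole magnitudes and axis lengths are convention-bound
  (origin; λ→length mapping); compare like with like, and expect
  calibration to be needed against any externally produced trajectory.
* No electronic polarizability anywhere: charges are fixed numbers.
* PDB parsing keeps the first model and altloc A only; unresolved residues
  are simply absent, and all charge/dipole sums run over resolved atoms.
* The lattice model is a two-parameter rescaling, not a lattice sum; it
  inherits whatever approximations produced its calibration constants.
* GRO parsing covers the fixed-column coordinate format without velocities.
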