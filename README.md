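# tubupol

Post-processing toolkit for molecular-dynamics trajectories of highly
charged proteins under intense nanosecond electric fields, built around the
αβ-tubulin heterodimer — the microtubule building block whose unusually
large structural charge (≈ −33 e with C-terminal tails) and dipole moment
(thousands of debye) make it a natural target for field manipulation.

The package is for structural-bioinformatics and biophysics users who have
trajectories (or want synthetic stand-ins) and need the field-response
observables: protein shape, internal-frame dipole components, per-residue
and binding-site dipolar shifts, C-terminal-tail polarization, and the
downstream microtubule-lattice energy bookkeeping.

## What it computes

**Ellipsoid shape and internal frame.** Each frame's atom cloud is fitted
by the positional covariance matrix

C = (1/N) Σₗ (rₗ − ⟨r⟩)(rₗ − ⟨r⟩)ᵀ

whose eigenvectors c₁, c₂, c₃ (eigenvalues λ₁ ≤ λ₂ ≤ λ₃) are the axes of
the best-fitting ellipsoid and define a body-fixed frame x′ = minor,
y′ = medium, z′ = major. Eigenvector signs are propagated frame-to-frame
(maximal dot product with the previous frame) so the frame is continuous,
right-handed and reproducible. Axis lengths default to uniform-solid
semi-axes aᵢ = √(5λᵢ); the convention is stamped on every output.

**Dipole moments.** μ = Σᵢ qᵢ(rᵢ − O) in debye (48.0321 D per e·nm), for
the whole protein, any residue selection (C-terminal tails, drug-binding
sites) or single residues, from force-field partial charges or pH-7 formal
charges. Because tubulin is net-charged the dipole is origin-dependent:
the default origin is the selection's center of mass and the convention is
recorded on every result. Expressed in the internal frame, the dipole
sheds rigid roto-translational motion, so its drift is genuine
polarization; the y′ (medium-axis) component is the most field-sensitive.

**Trajectory statistics.** Last-window segment means ± SD (default 5 × 1 ns
segments from the final 5 ns), strided last-window histogram samples
(250 frames at 20 ps), per-residue dipolar-shift maps between exposed and
reference runs with exceedance counts (±5 D), coil counts of externally
assigned secondary structure, and per-site dipole reports.

**Lattice energetics.** The microtubule-lattice balance
E_dd(μ) = 27·(μ/4500)² kcal/mol (destabilizing dipole-dipole term) plus a
lumped baseline B = −36 kcal/mol: G(μ) = B + E_dd(μ), with the stability
threshold μ* = 4500·√(36/27) ≈ 5196 D.

**Synthetic trajectories.** A rigid, charged ellipsoidal body with
overdamped rotational Langevin dynamics (field torque μ×E plus rotational
diffusion) and a flexible acidic 20-residue tail whose stretch imposes an
exactly known internal y′ polarization with first-order relaxation — ground
truth for validating every pipeline stage without running MD.

## Worked example

```r
library(tubupol)

spec <- synthetic_spec(seed = 7)            # 30 ns, 20 ps step, 100 MV/m
prot <- make_ellipsoid_protein(spec)
prot
#> synthetic_protein: 2024 atoms (20 tail), total charge -33 e,
#>   imposed y' shift -40.00 D at 100 MV/m (seed 7)

exposed   <- simulate_trajectory(prot)                 # 100 MV/m along z
reference <- simulate_trajectory(prot, field_MV_m = 0)

ctt <- select_ctt(prot$model, "B")                     # 20-residue tail
se <- observable_series(exposed$trajectory,   prot$model, prot$charges, selection = ctt)
sr <- observable_series(reference$trajectory, prot$model, prot$charges, selection = ctt)

segment_stats(se$time_ps, se$muy)
#> segment_stats: mean -173.3 +/- 1.4e-10 (N = 5 segments, 5 ns window)
segment_stats(sr$time_ps, sr$muy)
#> segment_stats: mean -133.3 +/- 4.3e-14 (N = 5 segments, 5 ns window)
```

The exposed-minus-reference difference of the last-window y′ means, −40.0 D,
recovers the generator's imposed tail polarization exactly: the field pulls
the charged tail outward along the medium axis, and the internal-frame
transform isolates that polarization from the simultaneous rigid tumbling
of the body. The medium semi-axis in the reference run,

```r
segment_stats(sr$time_ps, sr$medium)
#> segment_stats: mean 2.82 +/- 8e-16 (N = 5 segments, 5 ns window)
```

reports the ellipsoid dimension under the stamped uniform-solid convention
(the resting tail inflates it slightly beyond the 2.65 nm body semi-axis).
Downstream, a dimer dipole of 3,000 D gives

```r
mod <- lattice_energy_model()
net_free_energy(mod, 3000)      # -24 kcal/mol, "stable"
stability_threshold(mod)        # 5196 D
```

so field-driven dipole growth beyond ≈5,200 D flips the lattice free energy
positive (at 6,000 D: +12 kcal/mol, unstable) — the proposed route by which
nanosecond pulses could disrupt microtubules.

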