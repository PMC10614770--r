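---
title: "The whole-nucleus chromatin model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The whole-nucleus chromatin model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleodyn)
```

# The model

`nucleodyn` simulates the interphase human nucleus as an interacting
particle system with four components:

* **Chromatin.** Each of the 46 chromosomes (22 autosome pairs plus X and
  Y in a male diploid genome) is a beads-on-a-string polymer with one bead
  per 100-KB genomic bin (bins are 0-based half-open; a trailing partial
  bin still gets a full bead).  Every bead carries a compartment label:
  *A* (euchromatin), *B* (heterochromatin) or *C* (pericentromeric).
* **Nucleoli.** Coarse-grained particles with mutual 12-6 Lennard-Jones
  attraction, so they condense spontaneously into a few liquid droplets.
* **Speckles.** Particles that interconvert between a phosphorylated (P)
  and a de-phosphorylated (dP) chemical state.  Only dP–dP pairs attract
  (Lennard-Jones); every pair involving a P particle is purely repulsive.
  The chemistry makes speckle droplets dynamic, non-equilibrium bodies.
* **Lamina.** A spherical shell of particles on a deterministic
  generalized-spiral (golden-angle) layout, bonded to their nearest
  neighbours so the mesh holds together.  In most runs the lamina is
  frozen and acts as the container; it is released for deformation runs.

All quantities are in reduced units: one length unit is σ = 385 nm, one
Brownian time unit is τ = 0.65 s, and the temperature is T = 1.  The
nuclear radius is 5 µm, i.e. 5000/385 ≈ 12.987 reduced units.

## Energy terms

The potential energy is a sum of:

1. **Backbone bonds** — harmonic, stiffness 30, rest length 1.
2. **Excluded volume** — a bounded soft core
   `E = e (1 − r/d)²` for `r < d` with height `e = 10` and particle
   diameter `d = 0.5` for every category.  The bounded height permits
   rare chain crossing, which greatly accelerates equilibration of
   entangled polymer melts without affecting contact statistics.
3. **Contact couplings** — every tunable chromatin interaction is a
   dimensionless coupling multiplying the smooth contact weight
   `f(r) = [1 + tanh(η (r_c − r))]/2`, shifted to zero at the cutoff
   `r_c + 4/η` so forces are continuous.  `f` is ½ at `r_c`, saturates
   at short range and is differentiable everywhere, which is what lets
   the same function serve as the observable in contact maps and as the
   energy kernel whose couplings the maximum-entropy loop adjusts.  The
   couplings are:
   * an *ideal* coupling `α(s)` depending only on genomic separation `s`
     along the same chromosome (a mean-field stand-in for
     loop-extrusion-driven compaction), tabulated up to `s_max` and
     clamped to the last value beyond;
   * a symmetric 3×3 *compartment* coupling over {A, B, C}, applied to
     every chromatin pair, which drives the microphase separation behind
     the Hi-C checkerboard;
   * a symmetric *chromosome-pair* coupling over haploid chromosome
     identities, applied to inter-chain pairs (homolog pairs map to the
     diagonal);
   * per-bead *landmark* couplings `χ_lam`, `χ_spk`, `χ_nuc` (indexed by
     haploid bin, shared by homologs) multiplying the contact weight to
     lamina, dP-speckle and nucleolus particles — the energetic mirrors
     of Lamin-B DamID, SON TSA-Seq and nucleolus-association profiles.
     Speckle couplings act on dP particles only.
4. **Body condensation** — Lennard-Jones with σ_LJ = 0.5 and cutoff
   2.5 σ_LJ (truncated and shifted), attractive for nucleolus–nucleolus
   and dP–dP pairs; all other body pairs interact through the repulsive
   branch truncated at the minimum.  Below 0.8 σ_LJ the potential
   continues linearly, so overlapping particles feel a large but finite
   force (important for random initial conditions).
5. **Confinement** — a harmonic penalty `k (r − R)²` outside the nuclear
   radius for non-lamina particles, a smooth backstop behind the
   particulate mesh (soft-core particles could otherwise slip between
   mesh vertices).
6. **Deformation** — an optional harmonic z-compression `½ k_z z²` on
   lamina particles for envelope-deformation runs.

Negative couplings are attractive; at coupling zero every tunable term
vanishes exactly, which reduces the model to confined ideal chains plus
body condensation — a property the test-suite uses heavily.

## Dynamics

Two stochastic integrators propagate the system with time step
dt = 0.005:

* **Langevin** (BAOAB splitting, unit masses) with damping γ⁻¹ = 10 —
  fast conformational sampling for ensemble building and optimization;
* **Brownian** (Euler–Maruyama) with γ⁻¹ = 0.01 — heavily damped motion
  mimicking the viscous nucleoplasm, used for dynamical observables; one
  time unit maps to τ = 0.65 s.

Every 4000 steps a semi-grand canonical Monte Carlo sweep makes `N_Sp`
reaction attempts (`N_Sp` = speckle count): each attempt picks a speckle
uniformly at random and proposes flipping its P/dP state with
probability 0.2.  By default the proposal is accepted by the Metropolis
criterion on the energy change, which preserves detailed balance at the
positional temperature and stabilizes dP droplets (a dP particle deep in
a droplet rarely dephosphorylates away); `metropolis = FALSE` flips
unconditionally for comparison.  Reactions never move particles or
change particle counts.

Production conventions: configurations are recorded every 2000 steps and
the first 500,000 steps of long runs are discarded as equilibration —
the discard is applied at analysis time (`trajectory_frames()`), never
baked into the trajectory files.

Random numbers come from a single 64-bit Mersenne-Twister stream per run
seeded by the user; trajectories are bit-reproducible from the seed, and
checkpoints carry the serialized generator state so a restarted run
reproduces an uninterrupted one exactly (neighbour lists rebuild on a
deterministic schedule — every 200 steps, with a displacement-triggered
safety rebuild — so the floating-point summation order is also part of
the reproducible state when segments align with the schedule).

## Maximum-entropy parameterization

Couplings are fitted by the standard maximum-entropy loop: simulate an
ensemble with the current couplings, extract the constraint averages
conjugate to each coupling block, compare with targets, update, repeat.
The five constraint blocks mirror the five coupling blocks one-to-one:

* mean contact by genomic separation (pairs beyond `s_max` pool into the
  clamped entry);
* the six unordered compartment-pair mean contacts;
* per-haploid-chromosome-pair mean inter-chain contact (homolog
  averaged);
* per-bin lamina and dP-speckle contact frequencies, computed as the
  union weight `1 − Π_l (1 − f(r_l))` over the landmark set — bounded in
  [0, 1], saturating for a bead permanently at the landmark.

Updates use Adam (defaults: learning rate 0.01, β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁸; per-block learning rates allowed).  With the energy convention
`E = α·f` the gradient of the maximum-entropy dual for a coupling is
`(experimental − simulated)` for its own average, so a contact that is
over-represented in simulation makes its coupling more repulsive and
vice versa; the gradient is exactly zero at perfect agreement.
Constraint entries with no sampled pairs contribute no gradient.

For real experimental inputs the package reads bedGraph tracks at their
native 25-KB resolution, merges replicates by bin-wise averaging and
rebins to 100 KB by averaging non-missing native bins; Hi-C summaries
enter as pre-exported dense or sparse 100-KB matrix text (the binary
Hi-C container toolchain stays outside this package).

## Observables

`compute_contact_map` (frame-averaged smooth contacts, optional homolog
collapse averaging the copy-pair combinations; the self-bin entry of a
collapsed map is pinned at the saturation weight `f(0)`),
`contact_scaling` (mean contact versus genomic separation),
`insilico_profile` (DamID-like lamina and TSA-Seq-like dP-speckle
contact frequencies, raw and z-scored), `compute_msd` (time-origin
averaged, physical units, log–log power-law fit `MSD = D_α Δt^α` over a
configurable window, default 10–1000 s; the fit is refused with fewer
than 5 lag points), `chromosome_geometry` (equal-mass radii of gyration
and normalized radial positions), `cluster_droplets` (single-linkage
connected components under a distance cutoff, default 1.5 σ_LJ = 0.75,
min droplet size 2), `ensemble_correlations` (pairwise Pearson over
upper triangles or profile vectors), and `lamina_shape` (principal axes
of the envelope in its centre-of-mass frame, sphericity and z/xy axial
ratio).

# The toy nucleus

Desk-scale work runs on a deterministic toy system
(`make_toy_nucleus()`): a few short diploid chromosomes with a stylized
compartment pattern (alternating A/B blocks, C-labelled chain ends),
nucleolus and speckle particles, and a lamina mesh.  Two scaling choices
matter:

* **Density, not size, is preserved.**  The toy's nuclear radius is
  chosen so the chromatin volume fraction matches the full-scale model
  (~0.43); droplet formation and territory compaction depend on packing
  density rather than absolute particle number.
* **The contact radius scales with the nucleus.**  At full scale
  r_c = 1.75 is a small fraction of the 13-unit radius; in a toy nucleus
  of radius ~2 it would span most of the volume and saturate every
  contact observable (a DamID-like profile would read 1.0 for every
  bead).  Toy force fields therefore default to r_c = 0.75, η = 8,
  keeping the contact geometry in proportion.

`make_synthetic_targets()` closes the loop for testing: it simulates the
toy with planted couplings and extracts the constraints, giving
optimization targets with known ground truth.  `make_track_fixtures()`
emulates the shapes of the experimental inputs (smooth anti-correlated
DamID-like and TSA-Seq-like tracks at 25 KB, two noisy replicates each).
All fixtures are pure functions of their seed.

What the toy does *not* emulate: realistic Hi-C checkerboards (the
compartment pattern is stylized blocks), chromosome-length heterogeneity,
sub-100-KB structure, and the slow conformational relaxation of a
full-size nucleus.  Tests passing on the toy demonstrate the machinery
(energies, dynamics, estimators, optimization) is correct, not that the
toy reproduces experimental biology.

# Numerical choices

* Time step 0.005 for both schemes; BAOAB gives accurate configurational
  statistics at this step (tethered-particle variance within ~1% of
  T/k in the test suite).
* Neighbour lists use per-category-pair cutoffs with a 0.3 skin; pair
  terms are skipped entirely for coupling blocks that are identically
  zero, so zero-coupling runs cost only the excluded-volume and body
  terms.
* Overlap safety: the soft core is bounded by construction; the
  Lennard-Jones branch continues linearly below 0.8 σ_LJ.  Non-finite
  coordinates or energies abort a run with a diagnostic naming the
  particle, after checkpointing the last finite frame.
* Initial configurations place each chromosome as a collapsed random
  walk in a random territory, bodies uniformly at random, followed by a
  brief capped steepest-descent relaxation (50 steps, displacement cap
  0.05) and a radial clamp back inside the enclosure.
* For dynamic-envelope (deformation) runs, `apply_deformation()`
  stiffens the mesh bonds to k = 1000 — the envelope must balance the
  osmotic pressure of the contents at volume fraction 0.43, which the
  frozen-mesh default k = 30 cannot — and removes the spherical
  confinement backstop so the mesh itself is the deforming container.
  Envelope shape is always measured in the lamina centre-of-mass frame,
  because the unanchored nucleus diffuses as a whole.
* Droplet-count conventions: a droplet is a single-linkage cluster of at
  least 2 particles at cutoff 0.75.  When quantifying *dispersal* of an
  initial random configuration the singleton-inclusive count is the
  informative number; a condensed state keeps a few monomers in exchange
  equilibrium with the droplet, which is liquid behaviour and not
  incomplete coarsening.
* Subset selection of starting configurations uses steepest-descent swap
  search (best improving swap over all outside candidates) from the best
  of several random initial subsets, restarted a few times; only
  improving swaps are accepted, so the objective trace is monotone and
  never worse than the best random initialization.

# Problem sizes used by the test suite

The packaged checks run at deliberately small scale: force-gradient
checks on ~100-particle toys; single-particle integrator physics with
100 replicas × 10⁴ steps (Brownian) and 10⁶ steps (Langevin tether);
phase-separation and deformation runs on the default 1010-particle toy
for 2×10⁵ and 3×10⁴ steps; and the maximum-entropy recovery experiment
on a 3-chromosome toy (364 particles) with 2 trajectories × 8000 steps
per iteration for 25 iterations, evaluated against an independent
3-trajectory validation batch.  These sizes were chosen so the full
suite exercises every code path in well under an hour on one core while
keeping each statistical assertion at ≥3σ resolution.  The same
machinery scales to the full 46-chromosome system (≈60,000 chromatin
beads plus bodies and lamina) with the default parameters; full-scale
ensembles simply need cluster-scale compute and the experimental target
files.

# Known limitations

* Loop extrusion is represented only through the ideal-by-separation
  coupling; there are no explicit motors.
* No hydrodynamic interactions, electrostatics, or nuclear pore
  complexes.
* The lamina mesh has stretching but no bending stiffness; without
  internal contents a dynamic envelope would crumple.
* Hi-C normalization pipelines (matrix balancing and count-to-probability
  calibration) are out of scope: experimental summaries enter as
  preprocessed text matrices, and landmark tracks are mapped onto the
  simulated contact-frequency scale by quantile mapping at the user's
  choice.
* Uncertainty quantification of fitted couplings is not attempted.
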