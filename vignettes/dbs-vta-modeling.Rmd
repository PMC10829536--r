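---
title: "Volume-conductor DBS modeling: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-conductor DBS modeling: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dbsvta)
```

This vignette documents the model, its assumptions, the tunable
parameters, what the synthetic data generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.
It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The model

Deep brain stimulation delivers current pulses through an implanted
electrode; the therapeutic effect is believed to track which axons near
the contact are driven to fire. The package implements the standard
two-stage estimate:

1. a **quasi-static volume conductor model**: at the low frequencies of
   DBS pulses, capacitive and inductive effects in tissue are neglected
   and the extracellular potential obeys the elliptic equation
   \(\nabla \cdot (\sigma \nabla \varphi) = 0\) with the tissue
   conductivity \(\sigma(\mathbf{x})\) piecewise constant per tissue
   class;
2. an **activation-function threshold**: for a straight axon the driving
   term of the cable equation is the second directional derivative of
   \(\varphi\) along the fiber. Without fiber orientation data, the most
   excitable orientation at a point is the eigenvector of the Hessian
   \(H_{ij} = \partial^2 \varphi / \partial x_i \partial x_j\) with the
   algebraically largest eigenvalue \(\lambda_1\) ("primary"
   eigenvalue). The volume of tissue activated (VTA) is the region
   \(\lambda_1 \ge T\).

The default threshold is \(T = 26.6\ \mathrm{V/cm^2}\), the published
value for myelinated axons of 5.7 µm diameter with 70 Ω axoplasmic
resistivity at the clinical pulse width. No axon cable model is
evaluated here: \(T\) is a configurable constant (stored internally in
V/m², conversion factor exactly \(10^4\)), and no pulse-width- or
diameter-dependent recalculation is attempted.

Because the problem is linear, monopolar stimulation is solved with a
unit Dirichlet potential on the active contact (the physically correct
equipotential-metal condition) and the solution rescaled so the total
emitted current equals the programmed amplitude. The electrode–IPG
impedance is then a by-product, \(R = V_c / I\), which makes the
clinical impedance measurement usable as a calibration target.

## Tissue model and parameters

| Tissue | σ (S/m) | role |
|---|---|---|
| Average body (scalp/neck slab) | 0.400 | carries the return current |
| Skull | 0.300 | resistive shell |
| Gray matter | 0.120 / 0.090 (patients 1 / 2) | **calibrated** per patient |
| White matter | 0.058 | bulk brain |
| CSF | 1.800 | conductive shunt |
| Ventricle | 0.300 | deep CSF space stand-in |
| Lead shaft | 0 | exact insulator (excluded from the unknowns) |
| Non-active contacts | 4·10⁶ | passive metal |

Gray matter is the single calibrated parameter because it is the tissue
the active contact sits in and the one the published per-patient tables
actually vary; all other tissues stay pinned. Calibration brackets
σ_GM in [0.02, 0.5] S/m and bisects (≤ 60 iterations, default relative
impedance tolerance 0.5%, well below clinical impedance repeatability);
impedance is strictly decreasing in σ_GM, which the tests assert, so
bisection is guaranteed and deterministic.

The lead is an Abbott 6172-style directional array: 8 contacts of height
1.5 mm on a 0.635 mm-radius shaft, edge-to-edge spacing 1.5 mm, ordered
distal ring / 3 segments / 3 segments / proximal ring, contact 1 (left)
or 9 (right) the distal ring. Published sources do not state the segment
arc; 100° arcs with 20° gaps are used (three 120° pitches, the common
directional-lead convention). This choice is irrelevant to the shipped
fixtures, whose active contact is a ring. Contacts are rasterized as
one-voxel-thick shells at the lead surface (at coarse spacing the
sub-voxel cross-section collapses to a single column); when a sub-voxel
contact falls between lattice planes the voxel nearest the contact
centroid is claimed so the source never vanishes.

## Discretization and solver

* Finite volumes on the voxel grid, harmonic-mean face conductivities —
  the discrete form of flux continuity across tissue interfaces. The
  scheme is conservative: the tests check that the net current through
  any closed voxel surface around the contact equals the injected
  current to 0.5%.
* σ = 0 voxels are removed from the unknown set rather than given a tiny
  conductivity: insulation is exact and the system stays well
  conditioned.
* Conjugate gradients, matrix-free over a compact index list of free
  voxels, preconditioned with modified IC(0) (Gustafsson diagonal
  compensation, ω = 0.95). Relative residual ≤ 1e-8, cap 50 000
  iterations; typical head-phantom solves converge in 100–250
  iterations.
* **Local refinement**: a 20–22 mm cube around the contact is re-solved
  at 0.25 mm with labels resampled (and the lead re-rasterized from
  geometry), Dirichlet face values trilinearly interpolated from the
  coarse solution. By default the face values are kept exactly, so fine
  and coarse agree on the box boundary (asserted ≤ 5%). When the
  *refined impedance* is itself the target (sub-voxel contacts, e.g. the
  spherical-contact verification toys), an optional fixed-point coupling
  rescales the face data to the fine contact current — face potentials
  are linear in the current that generated them — which converges
  geometrically because the far-field resistance is a minor fraction of
  the total.
* The adaptive tetrahedral meshing of commercial FEM is out of scope;
  fixed two-level grids plus grid-convergence tests (impedance and VTA
  volume under spacing halving) replace it.

## VTA numerics

The refined potential is interpolated onto a regular 20 mm cube at
0.1 mm (a `--fast` 0.2 mm mode exists for CI-scale runs; the volume
discretization error roughly doubles). Second derivatives use
second-order central differences; the symmetric 3×3 eigenproblem is
solved in closed form per node. The one-node border is invalid, and an
exclusion shell — the lead radius plus two fine voxels plus one source
voxel — removes nodes whose stencils straddle the conductor/insulator
boundary, where finite differences are meaningless. Excluded volume is
small (the lead interior plus ≈ 0.5 mm of shell) and is added back
analytically in oracle comparisons. Negative-λ₁ regions need no special
treatment: they fall below any positive threshold.

Unit conventions: grids are in world millimetres (right-handed,
voxel-center convention, 0-based world algebra / 1-based R indices);
potentials in volts; all Hessian quantities in V/m² (spacing converted
internally); conductivities in S/m; currents in amperes; volumes in mm³.

## The synthetic world

The generator replaces patient imaging with a stated, reproducible
world:

* **Head phantom**: nested ellipsoids (scalp, skull, CSF, gray-matter
  shell, white matter, ventricles) plus a deep-gray ellipsoid around the
  implant target — the basal-ganglia stand-in that puts the active
  contact in gray matter, as in the clinical anatomy — and a body slab
  below the head whose bottom face carries the current sink. Total
  extent 140×140×180 mm at 1.5 mm spacing (≈ 1.07 M voxels), chosen so
  all six tissue classes are present and a calibration run stays at
  desk scale.
* **Lead trajectory**: an oblique frontal approach with the tip inside
  the deep-gray compartment; left and right are mirror images.
* **Pseudo-CT artifact**: the hyperdense blooming a metal lead leaves in
  CT, emulated as a cylinder of high intensity (lead radius + half a
  voxel of blur) plus additive Gaussian noise (SD 50 intensity units
  against a 1000-unit artifact) under a fixed seed. Any unimodal noise
  suffices for the round-trip requirement (fitted axis within 2° of
  truth); the default SD keeps the thresholded mask clean while
  exercising the fit.
* **Target nucleus**: an ellipsoid of semi-axes 4.9 × 6.2 × 4.0 mm
  (≈ 509 mm³ — accumbens-scale; per-patient nucleus volumes are not
  published, only overlap percentages, which imply a few hundred mm³),
  centered 7.0–7.8 mm medial to the active-contact centroid depending on
  patient and side. The offsets were fixed once from the closed-form
  sphere-overlap estimate so the fixtures land in the published
  few-mm³ overlap regime with patient 1's right side the largest; the
  suite asserts only the *ordering* (larger right-side overlap goes with
  the larger printed improvement), not the clinical values.
* **Patient records**: the published stimulation settings, measured
  impedances and pre/post Y-BOCS scores of the two study patients.

What a green test does **not** establish: real anatomy (no gyri, no
anisotropic white matter, no electrode–tissue encapsulation layer), real
CT physics, per-patient absolute VTA and overlap values (those depend on
the unavailable clinical images), or any statistical clinical claim
(n = 2 in the source study; none is made here either).

## Verification strategy

Every numerical stage is held against an independent closed form:

* point source in a uniform medium: \(\varphi = I/(4\pi\sigma r)\); on
  the bounded test domain (grounded spherical shell at \(R_{out}\)) the
  exact solution is \(I/(4\pi\sigma)(1/r - 1/R_{out})\), so solver
  output is compared after adding back the known truncation constant —
  the comparison then isolates pure discretization error (≤ 2% at
  r = 3 mm);
* spreading resistance of a spherical contact: \(R = 1/(4\pi\sigma a)\),
  inverted by the calibration toy to recover σ within 5%;
* Hessian of \(k/r\): eigenvalues \((2k/r^3, -k/r^3, -k/r^3)\), λ₁
  within 1%;
* point-source VTA: radius \((2k/T)^{1/3}\), volume \(2I/(3\sigma T)\)
  (= 114.9 mm³ at 5.5 mA, 0.12 S/m, 26.6 V/cm²), within 5% at 0.1 mm;
* sphere–sphere overlap lens: \(\pi(4r+d)(2r-d)^2/12\), within 3%.

Properties asserted across generated cases: determinism under fixed
seeds, current conservation, the discrete maximum principle, linearity
in the injected current, reciprocity of source and sink, invariance
under tissue relabeling and axis permutation, monotonicity of VTA volume
in threshold and current, monotonicity of impedance in σ_GM, and grid
convergence of impedance and VTA volume.

## Degenerate inputs and tie-breaks

* Empty artifact masks, non-elongated masks (principal-extent ratio
  < 3), degenerate ellipsoids, empty nuclei, targets outside the
  impedance bracket, disconnected source/sink, and sampling boxes
  exceeding the solved grid all raise informative errors.
* The distal lead end is disambiguated by the lower-z rule (deeper in
  the phantom), configurable; the clinical chain resolves this visually.
* Equal Hessian eigenvalues tie arbitrarily — the threshold test is
  unaffected.
* Patient 2 has two measured impedances (1262/1150 Ω) but published
  tables print a single σ_GM; the pipeline calibrates each side
  independently and reports both.

## Known limitations

* Voxelized geometry: staircase contacts limit absolute impedance
  accuracy at coarse spacing; the calibration absorbs this into σ_GM
  (which is also what the clinical procedure's calibration does with its
  own unmodeled pathway impedances), and the refined two-grid evaluator
  exists where the absolute value matters.
* DC conduction only — no tissue dispersion, no electrode double layer.
* The VTA is a field-threshold estimate, not an axon population model;
  pathway-specific activation is out of scope.
* The body slab and sink placement are stand-ins; published sources do
  not describe the torso geometry, and only the far-field resistance is
  affected.
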