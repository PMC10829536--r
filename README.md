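# dbsvta

Patient-specific volume-conductor modeling of deep brain stimulation
(DBS) on voxelized head models, with volume-of-tissue-activated (VTA)
estimation and clinical outcome scoring.

## Who this is for

Computational neurostimulation researchers who want a desk-scale, fully
scriptable stand-in for the classic patient-specific DBS modeling chain
(MRI/CT segmentation → FEM field solve → activation-function
thresholding) without commercial FEM software or clinical imaging data.
Everything the clinical chain obtains from imaging is replaced here by a
tested synthetic head-phantom generator, so every stage runs and is
verifiable offline.

## What it computes

For a monopolar stimulation setting (one cathodic contact of a
directional 8-contact lead, distant implantable-pulse-generator case as
anode):

1. **Volume conductor solve.** The quasi-static potential
   `∇·(σ∇φ) = 0` is discretized by finite volumes on a voxelized
   tissue-label grid with harmonic-mean face conductivities. The active
   contact is an equipotential Dirichlet surface (1 V, then rescaled by
   linearity so the emitted current matches the programmed amplitude);
   the bottom face of the body slab is the grounded return; all other
   exterior faces are zero-flux; σ = 0 voxels (lead shaft, air) are
   excluded exactly. The solver is a matrix-free conjugate-gradient
   iteration with a modified incomplete-Cholesky preconditioner
   (relative residual ≤ 1e-8).
2. **Impedance calibration.** The electrode–IPG impedance falls out of
   the solve as `R = V_contact / I`. Gray-matter conductivity σ_GM is
   bisected (all other tissues pinned to their table values) until the
   simulated impedance matches the clinically measured one.
3. **VTA.** The potential is re-solved on a locally refined box around
   the contact, interpolated onto a regular 20 mm cube at 0.1 mm, and the
   3×3 Hessian of φ is formed by central differences at every node. The
   *activation function* along the most excitable axon orientation is the
   algebraically largest (primary) eigenvalue λ₁ of the Hessian; the VTA
   is the region λ₁ ≥ 26.6 V/cm² (= 2.66e5 V/m²), excluding a small shell
   around the electrode body where finite differences are meaningless.
4. **Outcome scoring.** VTA volume, overlap with a target nucleus
   (nucleus accumbens stand-in), percent of target covered, and percent
   improvement `100·(pre − post)/pre` of the Y-BOCS score.

Closed forms anchor the numerics throughout: a point source in a uniform
medium has `φ = I/(4πσr)`, Hessian primary eigenvalue `2k/r³` with
`k = I/(4πσ)`, spreading resistance `1/(4πσa)` for a spherical contact,
and a VTA volume of exactly `2I/(3σT)`. The test suite holds the solver,
eigenvalue field, impedance and VTA against all of these.

## Worked example

A full pipeline run for patient 1's right lead on a coarsened grid
(2 mm phantom, fast 0.2 mm VTA mode; the default is 1.5 mm / 0.1 mm):

```r
library(dbsvta)
res <- run_pipeline(pipeline_config(patient = 1, side = "right",
                                    fast = TRUE, phantom_spacing = 2))
res$report
```

```
  patient  side active_contact current_mA target_impedance_ohm
1       1 right              9        5.5                  926
  achieved_impedance_ohm sigma_gm_S_per_m vta_mm3 overlap_mm3 percent_of_target
1               929.7768         0.108125  96.472        6.12          1.320605
  ybocs_pre ybocs_post percent_improvement
1        31         10                  68
```

Reading the row: the lead was localized from a synthetic CT artifact,
contact 9 (the right distal ring) drives 5.5 mA; gray-matter conductivity
was calibrated to 0.108 S/m so the simulated electrode–IPG impedance
(929.8 Ω) matches the measured 926 Ω within 0.5%; the resulting VTA is
96 mm³ of which 6.1 mm³ (1.3% of the nucleus) falls inside the target;
the patient's Y-BOCS score improved 68% (31 → 10).

Individual stages are exposed as ordinary functions
(`build_head_phantom`, `fit_trajectory`, `build_lead`, `rasterize_lead`,
`solve_potential`, `calibrate_gm_conductivity`, `refine_local`,
`sample_grid`, `hessian_primary_eigenvalue`, `threshold_vta`,
`overlap_volume`) — see the vignette source in `vignettes/` for the
modeling details and numerical choices.

A small command-line front end lives at `inst/cli/dbsvta.R`:

```sh
Rscript inst/cli/dbsvta.R fixture --patient 1
Rscript inst/cli/dbsvta.R pipeline --patient 1 --side left --fast --out results/
```

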