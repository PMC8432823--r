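# t2accel

Simulation and evaluation pipeline for **accelerated 3D whole-heart
cardiac T2 mapping**. The package answers a practical protocol-design
question: when the phase-encode plane of a multi-echo (T2-prepared) 3D
acquisition is undersampled to save scan time, *how do the fitted T2
maps degrade — and which combination of sampling pattern and
reconstruction preserves them best?*

It is aimed at MR-physics and image-reconstruction researchers who
want a reproducible, fully synthetic test bed for multi-contrast
parallel-imaging experiments.

## What is inside

**Signal model.** Each voxel decays mono-exponentially with the
T2-preparation time, S(TE) = A0·exp(−TE/T2), sampled at
TE = 0, 25, 35, 45 ms. Voxelwise log-linear regression
(ln S = ln A0 − TE·R2, T2 = 1/R2) recovers the maps; voxels with
T2 < 15 ms or T2 > 100 ms count as unsuccessfully recovered.

**Phantom** (`phantom_spec()`, `make_phantom()`, `simulate_kspace()`):
a short-axis-like slab — annular myocardium (T2 = 44 ms), blood pool
(250 ms), body (35 ms), optional edematous sector (60 ms) — with
smooth RSS-normalized coil sensitivities and white complex Gaussian
k-space noise, under centered unitary FFTs.

**Sampling** (`make_es()`, `make_caipi()`, `make_vdr()`,
`match_vdr_to_caipi()`): equally spaced lattices, CAIPIRINHA-style
sheared lattices with per-echo interleave cycling, and
variable-density random patterns drawn from a Gaussian radial density
(σ = 0.5 × max k-space radius) — all with a fully sampled central ACS
block, an elliptical corner shutter, and exact net-reduction-factor
(`compute_rnet()`) accounting.

**Reconstruction** (`recon_reference()`, `recon_traditional_sense()`,
`recon_mv_sense()`, `recon_js_sense()`, `recon_mb_sense()`): RSS
reference, volume-by-volume and joint CG-SENSE
(min ‖DEI − k‖²), joint-total-variation regularized SENSE
(+ λ‖I‖_JTV, λ = 0.1), and model-based SENSE, which alternates robust
projection onto the exponential-decay manifold with Tikhonov-shifted
data-consistency solves (λ = 0.5).

**Metrics** (`nrmse()`, `t2_bias_sd()`, `otsu_threshold()`,
`jaccard()`, `pct_unrecovered()`): image/T2 NRMSE against the fully
sampled reference, T2 bias and SD over the myocardial ROI,
Otsu-threshold edema segmentation with Jaccard overlap, and the
unrecovered-voxel percentage.

**Pipeline** (`experiment_config()`, `run_cell()`, `run_grid()`):
the full scheme × method × ORF × seed grid with paired noise/pattern
seed streams, VDR repeat averaging and CSV output. A thin CLI lives at
`inst/cli/t2accel.R`.

## Worked example

One cell of the experiment grid: variable-density random sampling at
outer reduction factor 3, jointly reconstructed with CG-SENSE on a
reduced 32×32×8 phantom:

```r
library(t2accel)
cfg <- experiment_config(phantom = phantom_spec(grid_shape = c(32, 32, 8),
                                                n_coils = 4),
                         recon_args = list(max_iter = 15))
run_cell(cfg, "VDR", "mv_sense", orf = 3, seed = 1)
```

```
  scheme   method orf seed pattern_seed     rnet nrmse_image nrmse_t2   t2_bias
1    VDR mv_sense   3    1            1 1.384058    5.600274 8.888475 0.5529107
     t2_sd jaccard pct_unrecovered status
1 3.939069      NA               0     ok
```

Reading the row: with a net reduction factor of 1.38 the reconstructed
images deviate from the fully sampled reference by 5.6% (NRMSE inside
the left-ventricular ROI) but the T2 map deviates by 8.9% — parametric
maps degrade faster than the images they are fitted from, the study's
central qualitative finding. The mean myocardial T2 is nearly unbiased
(+0.55 ms) while the spatial SD (3.9 ms) reflects the noise
amplification of the accelerated reconstruction; every ROI voxel
stayed inside the 15–100 ms validity band (`pct_unrecovered = 0`).
`jaccard` is `NA` because this phantom has no edematous lesion to
segment. (The reduced 15-iteration CG budget trips a non-convergence
warning; the full-size defaults in `recon_config()` do not.)

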