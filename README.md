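# habqsm

Quantitative susceptibility mapping (QSM) analysis of the human habenula,
packaged as a tested, reusable R pipeline.

The habenula is a small (~30 mm³ per side) epithalamic nucleus next to the
3rd ventricle. On high-resolution 3 T multi-echo gradient-echo (GRE) MRI it
often — but not always — shows elevated magnetic susceptibility,
concentrated in its posterior subregion, and thalamic veins one or two
pixels wide are a major confounder for any statistic computed inside it.
This package implements the full analysis chain needed to study that
contrast quantitatively, together with a digital phantom that makes every
step testable against known ground truth:

- **phantom** — a bilateral ellipsoidal habenula pair with a posteriorly
  localized susceptibility elevation, thin paramagnetic vein tubes, a CSF
  reference prism, smooth coil sensitivities, a harmonic background field,
  and complex multi-channel multi-echo GRE simulation. Susceptibility and
  R2\* derive from iron and myelin concentration fields via the two-source
  model (positive coefficients a, b, f, g):

  Δχ = a·c_Fe − b·c_m,  ΔR2\* = f·c_Fe + g·c_m

  so iron variation correlates the two maps positively and myelin variation
  negatively — the sign logic used to interpret in vivo data.
- **recon** — coil combination by TE = 0 receiver-phase extrapolation,
  Laplacian phase unwrapping, V-SHARP background-field removal (variable
  spherical-mean-value kernels + truncated deconvolution), dipole inversion
  (TKD and a two-pass streaking-reduction scheme), and mono-exponential R2\*
  fitting of Rician-noise-corrected magnitudes, plus a diagnostic for the
  R2\* bias caused by intravoxel field gradients.
- **roi** — vein-candidate detection, minimum-vein slice selection (≥ 16
  in-plane voxels, maximal distance from vein-like features), automated
  posterior-edge adjustment, outer (noise-reference) ROI construction,
  anterior/posterior and medial/lateral halving, greedy 5-voxel peak
  cluster, CSF referencing.
- **metrics** — the four contrast-to-noise ratios
  (CNR = Δχ / σ_χ(outer ROI) for mean, peak, AP and ML contrasts),
  voxelwise χ–R2\* Pearson correlation and regression slope, two-way
  random-effects ICC for rater agreement, representative-scan selection for
  repeated sessions, and group summaries.
- **interface** — NIfTI I/O (RNifti), JSON sidecars, a small CLI
  (`inst/cli/habqsm`), and a packaged transcription of the published
  21-subject contrast table that drives the statistics layer.

## Worked example

```r
library(habqsm)

spec <- phantom_spec(seed = 42)       # 48 x 48 x 36 grid, 8 echoes, 4 channels
res  <- run_phantom_pipeline(spec)    # phantom -> GRE -> QSM/R2* -> ROI stats

res$slice                             # minimum-vein slice chosen for analysis
res$cnrs$bilateral
res$correlation
```

prints (seed 42):

```
       side dchi_mean cnr_mean dchi_peak cnr_peak dchi_ap cnr_ap dchi_ml cnr_ml sigma_outer
1 bilateral    0.0183     1.71    0.0271     2.57  0.0113   1.08 0.00393  0.339      0.0107

   n     r       p slope intercept degenerate
1 48 0.401 0.00476  48.8      23.1      FALSE
```

Reading this: on the chosen axial slice the habenula ROI is 0.018 ppm more
paramagnetic than the adjacent thalamus (outer ROI), the 5-voxel peak
cluster gives the strongest contrast (CNR 2.6), the posterior half is
brighter than the anterior (CNR 1.1), the lateral–medial split carries no
contrast, the outer-ROI noise is 0.011 ppm, and χ and R2\* correlate
positively (r = 0.40, slope ≈ 49 s⁻¹/ppm) — the signature of an iron-like
susceptibility source. That is exactly the phenomenology the phantom is
built to emulate.

The group-level statistics of the packaged 21-subject table:

```r
run_cli("reproduce-table1")
#> n = 21 subjects; mean visual score = 2.19
#> column means: dchi_mean = 0.0142, dchi_peak = 0.0452, dchi_ap = 0.0258 ppm; CNR_peak = 4.40
#> score-CNR Pearson correlations:
#>   cnr_mean  r =  0.4632  (p = 0.0345)
#>   cnr_peak  r =  0.6727  (p = 0.0008)
#>   cnr_ap    r =  0.7216  (p = 0.0002)
#>   cnr_ml    r =  0.1234  (p = 0.5940)
#> lateral-medial difference: t = 0.818, p = 0.423
```

The same pipeline is scriptable from a shell
(`simulate` → `recon` → `analyze` → `report`); see
`Rscript inst/cli/habqsm` for usage.

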