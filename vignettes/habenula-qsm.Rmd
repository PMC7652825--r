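---
title: "Habenula QSM: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habenula QSM: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the physical and
statistical models it implements, the parameters that matter, the numerical
conventions, and the choices made where several defensible designs existed.

## The problem

The habenula is a bilateral epithalamic nucleus of roughly 30 mm³ per side.
At 3 T with sub-millimetre voxels it frequently shows a positive magnetic
susceptibility contrast against the adjacent thalamus, localized in its
posterior subregion, but the effect varies strongly across individuals and
is easily corrupted by thin thalamic veins. Two questions drive the
analysis design: *is* a given habenula hyperintense on QSM (quantified by
contrast-to-noise ratios against several reference regions), and is the
source of the hyperintensity iron-like or myelin-like (read from the sign
of the voxelwise χ–R2\* association)?

The package implements the complete measurement chain for these questions
and a digital phantom that provides ground truth for every stage.

## Forward model and reconstruction

**Signal model.** For channel $c$, echo time $TE_e$ and voxel $r$:
$$S_{c,e}(r) = M_0(r)\,s_c(r)\,e^{-R_2^*(r)TE_e}\,
e^{i[\varphi_{c,0}(r) + 2\pi f_B(r) TE_e]} + \varepsilon,$$
with complex Gaussian noise $\varepsilon$ per channel, smooth complex coil
sensitivities $s_c e^{i\varphi_{c,0}}$, and the field offset
$f_B = f_0\,(d \ast \chi) + f_{bg}$ composed of the dipole convolution of
the susceptibility distribution and a harmonic background. Units are ppm,
Hz, seconds and s⁻¹ throughout; with $f_0$ in MHz the conversion is simply
$f[\mathrm{Hz}] = \chi[\mathrm{ppm}] \cdot f_0[\mathrm{MHz}]$ (123.2 at
3 T).

**Dipole kernel.** The unit dipole transfer function has the continuum form
$D(k) = 1/3 - (k\!\cdot\!\hat B)^2/|k|^2$ with $D(0)=0$. The package
generates the kernel in *image space* — the Lorentz-corrected point dipole
$(3\cos^2\theta - 1)/(4\pi r^3)$ sampled at voxel offsets, zero at the
origin, scaled by the voxel volume, then FFT'd — rather than sampling
$D(k)$ analytically. Sampling $D(k)$ aliases badly for point-like sources
(errors above 100% along the principal axes), whereas the image-space
kernel makes FFT convolution agree with the direct spatial dipole sum to
machine precision; the two constructions share the same continuum limit.
All FFT convolutions zero-pad to the next power of two with at least 8
voxels of margin to suppress circular wrap-around; the torus (unpadded)
convention is available via `pad = FALSE`, under which a uniform
susceptibility produces exactly zero field.

**Coil combination.** Per channel, the echo-train phase is temporally
unwrapped (nearest-$2\pi$ correction echo to echo — safe for
$|f_B| < 100$ Hz at 5 ms echo spacing) and fitted against TE by
magnitude-weighted least squares; the intercept estimates the receiver
phase at TE = 0, which is subtracted before summing channels.
Zero-magnitude voxels get intercept 0 and are counted in an attribute.

**Phase unwrapping.** The Laplacian method solves
$\nabla^2\varphi_u = \cos\varphi\,\nabla^2\sin\varphi -
\sin\varphi\,\nabla^2\cos\varphi$ spectrally. The raw spectral solution
low-pass-distorts fine phase structure, so by default the result is snapped
back onto the measured phase plus the nearest multiple of $2\pi$
(`integer_correction = TRUE`): the spectral solve determines only the wrap
counts, and the measured phase keeps its fine structure wherever those
counts are resolved. Fields are then obtained as the magnitude-weighted
slope of unwrapped phase over TE.

**Background removal (V-SHARP).** Spherical-mean-value kernels with radii
descending from `max_radius_mm` (default 25 mm, the protocol's value) in
2 mm steps down to twice the largest voxel dimension are applied where they
fit entirely inside the brain mask, each voxel using the largest feasible
radius; radii that fit nowhere are skipped automatically, so the default is
usable on small phantoms. The filtered field is deconvolved by the largest
applied kernel with the factor truncated to zero where
$|1 - S(k)| < 0.05$. The output lives on the mask eroded by the smallest
radius. Harmonic fields from outside sources are strongly suppressed
(tested against a dipole source placed outside the mask); the residual
attenuation of genuine local fields is one reason reconstructed contrasts
sit somewhat below truth.

**Dipole inversion.** `tkd` divides by the kernel with $|D| < \delta$
replaced by $\mathrm{sign}(D)\,\delta$ (default $\delta = 0.1$, a common
published choice). `star2pass` (default) mirrors two-pass
streaking-reduction schemes: a strongly truncated pass
($\delta_{strong} = 0.3$) isolates high-$|\chi|$ sources (above the 99th
percentile), their forward field is subtracted, the remainder is inverted
with the weak threshold, and the components are summed. Maps are demeaned
over the mask; the zero point is fixed later by CSF referencing. Absolute
susceptibility values are method-dependent — a known property of dipole
inversion — so accuracy is judged on phantom recovery of *contrasts*, not
on matching any particular algorithm voxel for voxel.

**R2\* fitting.** Magnitudes are Rician-corrected with the first-moment
form $\tilde M = \sqrt{\max(M^2 - \sigma^2, 0)}$, which is approximately
unbiased for the underlying signal at moderate SNR, then
$S_0 e^{-R_2^* TE}$ is fitted per voxel by a vectorized damped Gauss–Newton
with log-linear initialization. (The second-moment form $M^2 - 2\sigma^2$
removes the bias of the *squared* magnitude but, through the Jensen effect
of the square root, leaves a larger R2\* bias than no correction at all in
Monte-Carlo tests; the first-moment form is both smaller in bias and the
standard magnitude-debiasing choice.) Echoes driven to zero are excluded;
voxels with fewer than 3 usable echoes are flagged with a sentinel, never
an exception. $\sigma$ can be estimated from the Rayleigh floor outside the
brain ($\sigma = \bar M / \sqrt{\pi/2}$). A separate diagnostic quantifies
the R2\* overestimation caused by intravoxel dephasing from a linear field
gradient (sinc magnitude modulation, refitted mono-exponentially); at the
deep-brain gradient scale of 1.6 Hz/cm across a 0.8 mm voxel this bias is
orders of magnitude below the 3% level, justifying the decision not to
apply gradient compensation.

## ROI machinery

All 2-D work happens on axial slices with axis 1 = left→right, axis 2 =
anterior→posterior, axis 3 = inferior→superior; slice indices are 0-based
internally in array terms (R's 1-based indexing) and reported 1-based.

- **Vein candidates**: voxels above background mean + 3 SD in either map,
  26-connected components, flagged when principal-axis elongation ≥ 3 and
  minor width ≤ 2 voxels (extents measured as PCA-projection ranges in
  voxel units). Connectivity choices (26 in 3-D, 8 in 2-D) are the
  permissive standards; "adjacent" is otherwise underdetermined.
- **Minimum-vein slice**: among slices with ≥ 16 in-plane ROI voxels and no
  vein voxel inside the ROI, maximize the minimum Euclidean distance (in mm,
  3-D, against all vein voxels); ties break by larger ROI area, then lower
  index. A "distance from veins" rule could be read in 2-D or 3-D, voxels
  or mm; 3-D distance in mm is the physically meaningful reading, and the
  implementation is verified against exhaustive per-slice scoring. If every
  slice is
  intruded, the maximum-distance slice is returned with a warning flag.
- **Posterior edge adjustment** is an automated surrogate for a manual
  step: one iteration adds posterior 4-neighbours whose first-echo
  magnitude lies within mean ± 2 SD of the ROI, capped at 15% growth
  (closest-to-mean candidates kept when the cap binds). The phantom's
  "segmentation" masks deliberately drop a seeded fraction (0.35) of
  posterior boundary voxels to emulate coronal-plane segmentation misses,
  so the adjustment has something real to recover.
- **Outer ROI**: the ROI shifted by half its bounding-box extent laterally
  (away from the midline) and anteriorly, minus the original. "Half its
  size" is read as half the bounding-box extent rounded to integer voxels —
  the only reading that gives a deterministic shift.
- **Peak cluster**: greedy growth from the maximum voxel, adding the
  highest-valued 8-adjacent in-ROI voxel four times; ties break by (row,
  column). On smooth peaked fields this greedy rule is exhaustively optimal
  (verified on ≤ 6×6 ROIs); on adversarial data greedy growth is not
  guaranteed optimal, which is why the optimality check uses
  habenula-like smooth fixtures.
- **Halving**: voxels sorted by AP coordinate (or distance from the
  midline), split at the count median, the odd voxel going to the
  posterior (resp. lateral) half; coordinate ties break by the orthogonal
  coordinate.
- **CSF reference**: mean susceptibility over a 3-slice CSF region centred
  on the analysis slice, subtracted exactly once (double referencing
  errors). Contrasts and CNRs are invariant under this offset.

## Statistics

CNRs divide each contrast by the outer-ROI susceptibility SD (degenerate
zero-SD input is an error). The χ–R2\* association uses Pearson r with the
two-sided t-test on n−2 df and the OLS slope of R2\* on χ; zero-variance
input yields a flagged, not fatal, result. Rater agreement uses ICC(2,1) —
two-way random effects, absolute agreement, single measure — computed from
the ANOVA mean squares; the consistency variant ICC(3,1) is available, as
the exact variant behind published values of this kind is rarely stated.
Representative-scan selection normalizes each of the four summary
parameters by its across-scan SD (zero-variance parameters contribute 0)
and minimizes the L1 sum of deviations from the scan average, ties to the
lowest index. Bilateral rows average left and right per quantity (each
side's CNR keeps its own noise denominator); recomputing from pooled ROIs
is possible by calling `compute_cnrs` on a combined mask. All p-values are
two-sided; no multiple-testing correction is applied.

## The phantom: what it emulates, and what it does not

Defaults emulate the 3 T protocol: TE 7–42 ms in 5 ms steps,
0.53 × 0.53 × 0.8 mm voxels, B0 along the slice normal, 123.2 MHz. The
habenula pair are ellipsoids (semi-axes 1.6 × 2.2 × 2.0 mm ≈ 30 mm³)
abutting a 0.5 mm midline gap; the posterior 40% of the AP extent carries
the susceptibility elevation (anterior +0.01, posterior +0.045 ppm over
thalamus). Veins are straight 0.4 mm-radius tubes (1–2 voxels wide after
rasterization) posterolateral to each habenula, spanning the superior half
of the volume so that inferior slices genuinely are "farther from veins";
vein χ is +0.3 ppm. A triangular CSF prism sits anterior to the habenulae
across ≥ 3 slices. The harmonic background field is scaled to SD 16 Hz over
the brain, matching the deep-brain B0 inhomogeneity scale of this protocol,
and the channel noise default (SD 5 at tissue M0 = 100, 4 channels) was
calibrated once so that the reconstructed outer-ROI susceptibility noise is
of order 0.011 ppm. R2\* defaults (base 18 s⁻¹, habenula ≈ 23–27 s⁻¹
through the two-source coefficients f = 95.8 s⁻¹ per unit c_Fe, g = 40,
a = b = 1) are plausible placeholders — R2\* magnitudes for this nucleus
are not well established, and the values are exposed as parameters of
`phantom_spec()` for exactly that reason.

The phantom does **not** emulate: whole-brain anatomy or air–tissue
interfaces (the background field is a smooth harmonic stand-in), k-space
acquisition, parallel-imaging or motion artifacts, partial-volume fine
structure beyond rasterization, or inter-subject anatomical variability.
Passing phantom tests therefore demonstrates that the *pipeline* is
self-consistent and recovers known contrasts under realistic noise — not
that any in vivo cohort value would be reproduced. Cohort-level statistics
are instead exercised through the packaged 21-subject contrast table.

Default problem sizes (48 × 48 × 36 grid, 8 echoes, 4 channels; 32³-scale
grids in unit tests) were chosen so a full pipeline run takes seconds while
keeping ≥ 3 usable habenula slices and a vein geometry that actually
constrains slice selection.

## Known limitations

- Absolute χ values are inversion-method dependent; only contrasts are
  validated against truth. V-SHARP plus TKD/two-pass inversion attenuates
  the habenula–thalamus contrast by roughly 10–25% on the noiseless
  phantom, which is asserted as an explicit budget rather than corrected.
- The posterior-edge adjustment is a deterministic surrogate for a manual
  step; its acceptance window and growth cap are design choices.
- The Laplacian unwrapper's integer correction assumes wrap counts are
  resolvable; in very low SNR regions it degrades to the raw spectral
  solution's behaviour.
- One cell of the packaged contrast table (volunteer 9, lateral–medial CNR)
  was corrupted in the available rendering of the source and is
  reconstructed from the printed column mean and SD; the printed
  score–CNR_ML correlation is consequently not exactly reproducible from
  the row data, though its substance (no association) is.
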