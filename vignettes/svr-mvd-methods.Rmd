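---
title: "Subvoxel-resolving reconstruction and multiview deconvolution: models and methods"
author: "svrmvd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subvoxel-resolving reconstruction and multiview deconvolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `svrmvd`: what each
stage assumes, which parameters matter, and where the numerical choices
came from. It complements the reference documentation of the individual
functions.

## The imaging problem

Selective plane illumination microscopy (SPIM) with a low-magnification
detection path can image a whole cleared organ in one field of view, but at
a strongly anisotropic resolution: the lateral width of the detection PSF
is set by the objective (about 4.2 µm FWHM for the configuration modelled
here) while the axial width is set by the light-sheet thickness (about
12 µm FWHM). Deep tissue additionally attenuates and scatters the
illumination, so each view darkens on its far side.

`svrmvd` implements the computational pipeline that turns such data into an
isotropic, resolution-enhanced volume:

1. **Tilted continuous scanning.** The stage translates the sample along a
   direction tilted away from the detection axis
   (`scan_geometry()`), with a per-frame step much smaller than the sheet
   thickness. Each 280 nm step tilted 10°/10° displaces the sample by
   ≈48 nm laterally and ≈272 nm axially, so consecutive frames carry
   subvoxel shifts relative to the voxel grid of the optics.
2. **Decimation into low-resolution groups.** Every `M`-th frame (phase
   *j*) forms one stack whose axial spacing matches the native optics
   (`grouping_plan()`, `extract_lr_groups()`); the `M` phases are mutually
   shifted copies of the same object.
3. **Subvoxel-resolving (SVR) reconstruction.** A multi-frame
   maximum-likelihood estimate fuses the groups on a finer grid
   (`run_svr()`), followed by a shear realignment that restores the true
   sample shape (`realign()`).
4. **Multi-view registration.** The sample is rotated about the vertical
   axis (8 views, 45° apart); bead or cell-body fiducials are detected,
   matched with rotation-invariant descriptors, and a rigid transform per
   view is fitted (`detect_features()`, `match_features()`,
   `fit_affine()`).
5. **Multiview deconvolution (MVD).** The registered views are fused by a
   weighted multiview Richardson–Lucy update with per-view PSFs
   (`run_mvd()`), producing the final isotropic estimate.

A full image-formation simulator (`simulate_multiview()`) generates
synthetic bead and filament phantoms through the same physics, so the
whole chain is testable end to end without an instrument.

## Forward model of one view

In the scan ("sheared") frame, where the frame index plays the role of the
axial coordinate, group *j* of one view is modelled as

$$ y_j = D\,S_{-\delta_j}\,H\,x + \varepsilon, $$

with $H$ a separable Gaussian blur (the PSF), $S_{\delta}$ a trilinear
subvoxel shift, $D$ block-average downsampling by the enhancement factors
$(r_x, r_y, r_z)$, and Poisson-dominated noise $\varepsilon$. Two
conventions deserve emphasis:

* **Offsets live in the sheared frame.** The stage displaces the sample by
  $j\,\mathbf d$ between phases, but in the sheared frame the lateral part
  of that displacement is absorbed by the shear: a bead's centroid moves
  between groups only axially, by $j\,r_z/M$ high-resolution voxels. The
  plan therefore carries both the nominal physical offsets ($j\mathbf d$ in
  HR voxels, used by the realignment bookkeeping) and the sheared-frame
  offsets actually seen by the solver. `estimate_offsets()` recovers the
  latter from the data by FFT cross-correlation with a full 3-D
  log-quadratic peak fit — the scan shear makes the correlation peak
  obliquely elongated, so the x–z cross terms of the quadratic are
  essential; per-axis interpolation is biased by more than half a voxel.
* **Blur before shift.** $H$ and $S$ commute in the continuous model; the
  implementation blurs first so one convolution per iteration is shared by
  all groups, and the streamed update is then *exactly* the sum of the
  per-group operators (the unit tests verify this against dense matrices).

The ML update is the multiplicative Richardson–Lucy form

$$ x \leftarrow x \cdot
   \frac{\sum_j S_{\delta_j} H\, U (y_j / \hat y_j)}
        {\sum_j S_{\delta_j} H\, U\, \mathbf 1}, $$

which preserves non-negativity and, on noise-free data, decreases the
Poisson data-fit divergence monotonically. An optional exponent
$q \in [1, 2]$ on the correction (`svr_config(acceleration = )`)
approximately squares the convergence rate; the pipeline presets use
$q = 2$. A multiplicative least-squares (ISRA) variant is available behind
`update = "leastsq"`.

## Shear realignment

The reconstruction lives in the sheared frame; `realign()` resamples it so
that structures straight along the sample's z become straight along the
volume axis. Each axial plane is displaced laterally by
$(M/r_z)\,(d_x, d_y)$ scaled to lateral voxels (≈1.0 voxel per plane for
the default optics). The realigned axial axis points opposite to the
sample's z (the scan sweeps the detection plane through the sample); all
views share the convention, so inter-view registration is unaffected.

## Registration

Bead-style registration needs only point constellations. Candidate
correspondences use the sorted distances to the 4 nearest neighbours
(rotation- and translation-invariant) with a 0.8 ratio test; a seeded
random-sample rigid consensus (1000 draws, 2 µm inlier radius) prunes
outliers, and the final transform is a least-squares (Kabsch) fit on the
inliers. Affine fitting is available for clearing-induced distortion;
rigid is the default since views differ by a rotation.

Quadratic interpolation of the difference-of-Gaussians peak localizes
blobs to ~0.2 voxel, which on a 2.3 µm axial grid is the registration
error budget; `refine_features()` therefore refits a 1-D Gaussian through
every feature along each axis, recovering centres to a few hundredths of
a voxel on blob-like structures. The pipeline registers on the
band-limited volumes described below.

## Multiview fusion

Each registered view contributes its volume $\phi_v$, a per-view PSF
$P_v$, and a content weight $w_v \in [0, 1]$. The simultaneous weighted
Richardson–Lucy update is

$$ \psi \leftarrow \psi \cdot
   \frac{\sum_v w_v\,\big[(\phi_v / (\psi \otimes P_v)) \otimes P_v^*\big]}
        {\sum_v w_v \otimes P_v^*}, $$

with $P_v^*$ the mirrored PSF. Weights multiply the correction and its
normalizer jointly, so masked content neither pulls nor bleaches the
estimate; with one all-ones view the update reduces exactly to classical
Richardson–Lucy (verified bitwise in the tests). A sequential scheme
(one view per sub-step) and a two-step vector extrapolation are available
through `mvd_config()`.

Per-view PSFs are anisotropic Gaussians in each view's own frame, rotated
into the reference frame by the fitted transform's rotation angle.
Convolution with a rotated Gaussian is implemented as rotate →
axis-aligned separable convolution → rotate back; poses that are multiples
of 90° are exact index permutations, other angles use trilinear
resampling. For the SVR-MVD pipeline the per-view PSF widths are
*measured* on each view's own reconstruction (bead FWHM medians), since
the SVR stage shrinks the effective PSF by an amount that depends on
convergence; the raw-volume ("conventional") fusion uses the optics PSF.

### Numerical safeguards

Three guards keep the simultaneous update stable on *real* (mutually
slightly inconsistent) views; all are configurable in `mvd_config()` and
all leave exactly consistent data untouched:

* **Background term** (`background_fraction`, default 0; the pipeline uses
  $10^{-3}$ of the view maximum): the ratio becomes
  $\phi / (\psi \otimes P + b)$. Gaussian tails are exponentially
  sensitive to any width mismatch between the modelled and effective PSF,
  and without $b$ the far-tail voxels see persistent ratios ≫ 1 that grow
  without bound.
* **Correction clamp** (`correction_clamp = 10`): bounds each iteration's
  multiplicative correction to $[0.1, 10]$.
* **Normalization floor** (`normalization_floor = 0.5`): near volume faces
  and mask edges the normalizer $\sum_v w_v \otimes P_v^*$ shrinks because
  kernel mass falls outside the observed region, and plain RL amplifies
  the truncated content; the floor caps that gain.

Two further choices matter at the fusion stage:

* **Axial band-limiting.** The SVR grid samples its own ~4.5 µm axial
  response at barely two samples per FWHM. Rotating such marginally
  sampled structure onto the isotropic fused grid creates interpolation
  texture (a bead centred between axial planes reconstructs as a flat-top
  that splits into two maxima under a 45° rotation) that the fusion model
  cannot represent. Each view is therefore smoothed by one axial voxel of
  Gaussian blur before registration and fusion
  (`pipeline_config(presmooth_axial_vox = 1)`); the PSF self-calibration
  happens *after* the smoothing, so the fusion model stays consistent.
  The single-view resolution report is measured on the unsmoothed volume.
* **Grid margin.** The fused grid extends ~10 µm beyond the bead-bearing
  region so that no significant intensity is truncated by the grid faces
  (truncated tails are the classic source of Richardson–Lucy edge
  artifacts). Voxels never sampled by any view are flagged through a
  coverage mask and simply stay at zero; voxels whose every observation
  was discarded by weights raise a coverage error.

## Content weights and attenuation

Depth-dependent attenuation is modelled as
$t(\text{depth}) = \max(e^{-\text{depth}/\ell}, \text{floor})$ along each
view's illumination axis. `view_weight_mask()` discards content beyond the
depth where $t$ falls below a threshold, with a cosine taper; opposing
views cover opposite sides, so the union of weights retains every voxel.
The attenuation length $\ell$ has no canonical value for cleared tissue
and is a free simulation parameter chosen per experiment; the bead
characterization runs without attenuation (beads in a clear medium).

## Metrology

`measure_fwhm()` samples a 1-D profile through a point, subtracts the
median of the profile's outer quartiles as background, and fits a Gaussian
by robust least squares (`optim`, Nelder–Mead then BFGS);
FWHM $= 2\sqrt{2\ln 2}\,\sigma$. Fits with $R^2 < 0.8$ raise an
unreliable-fit error; a half-maximum crossing mode is available as a
cross-check. `bead_resolution_report()` aggregates per-bead widths into
per-axis medians and IQRs and an isotropy ratio (median axial / median
lateral). Beads closer than 4× the expected FWHM to another bead are
flagged and excluded from aggregates; the boundary margin is 2× the
expected FWHM — exactly what the profile window needs — because a 4×
boundary margin would exclude every bead from any desk-scale field at the
12 µm raw axial width. Voxels integrate flux (the renderer is
flux-exact), so a measured width carries a small voxel-footprint term;
metrology-grade measurements should sample at ≥4 samples per FWHM.

## The synthetic generator, and what passing tests show

`simulate_scan()` renders each frame as the fixed detection-plane section
of the PSF-blurred phantom displaced by the accumulated scan steps, with
pixel-integrated lateral profiles (flux-exact for interior sources),
mid-step sampling of the continuous motion (second-order accurate for
steps ≪ sheet thickness), per-point attenuation at the source position,
and seeded Poisson plus Gaussian read noise. It deliberately omits:
physical scattering (only attenuation and a fixed blur), refractive-index
mismatch, spatially varying or non-Gaussian PSFs, stage jitter, and
photobleaching. Passing the resolution tests therefore shows that the
*algorithms* recover the modelled physics at the stated optics — not that
real tissue, with its aberrations and structured background, would yield
the same numbers.

## Study conditions and problem sizes

The bead-characterization preset (`pipeline_config()`) fixes the modelled
optics: 4.2/12 µm PSF, 280 nm steps tilted 10°/10°, native voxel
1.625 × 1.625 × 4.5 µm, 4 × 4 × 2 enhancement (reported reconstructed
voxel 1.625/4 ≈ 0.41 µm), eight views 45° apart, high SNR (peak ≈ 2000
counts, 2-count read noise), no attenuation. The field is desk-scale:
eight ~500 nm beads with ≥15 µm separation in a 65 µm cube, placed inside
a cylinder about the rotation axis so every view sees every bead; the
whole run takes on the order of ten minutes on one CPU. View 0 is
reconstructed to convergence (60 accelerated iterations) because it is
both the registration reference and the volume on which single-view
resolution is measured; the remaining views use 35 iterations, and the
fusion runs 28 iterations with the logged data-fit divergence confirming
the plateau. The conventional (no-SVR) fusion runs on a 2× coarser grid,
matching what its 4.2 µm optics can support.

## Known limitations

* The PSF is a separable Gaussian; real light-sheet PSFs have side lobes
  and depth dependence that would lower the attainable contrast.
* The SVR forward model ignores the small shear of the PSF in the scan
  frame (lateral displacement ≈0.18 of the axial offset within the sheet
  thickness); shape is restored by the realignment, but a fully sheared
  model could sharpen slightly further.
* Richardson–Lucy iterations sharpen beads below the nominal PSF width at
  high SNR; resolution figures quoted from bead fits are therefore tied to
  the logged iteration counts.
* Rigid registration assumes the sample does not deform between views;
  the affine mode absorbs uniform shrinkage only.
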