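# svrmvd

Isotropic, resolution-enhanced reconstruction for tilted-scan light-sheet
microscopy (SPIM), in R.

## The problem

Low-magnification light-sheet imaging of cleared organs trades resolution
for field of view: the detection optics limit the lateral width of the
point-spread function (PSF) to ≈4.2 µm FWHM and the light-sheet thickness
limits the axial width to ≈12 µm, and deep tissue attenuates each view on
its far side. `svrmvd` implements the computational pipeline that recovers
an isotropic, several-fold sharper volume from such data, together with a
full image-formation simulator and FWHM/SNR metrology, so the whole method
is testable end to end on synthetic phantoms.

The pipeline has three computational stages:

1. **Subvoxel-resolving (SVR) reconstruction.** The stage scans the sample
   continuously along a direction tilted ≈10° from the detection axis with
   a step (e.g. 280 nm) far below the sheet thickness. Each step shifts
   the sample by sub-voxel amounts (≈48 nm lateral, ≈272 nm axial), so the
   oversampled frame sequence decimates into M mutually shifted
   low-resolution stacks `y_j`. A multi-frame maximum-likelihood
   (Richardson–Lucy type) update fuses them on a finer grid:

       x <- x * [ Σ_j Aᵀ_j (y_j / A_j x) ] / [ Σ_j Aᵀ_j 1 ],
       A_j = D S_j H   (blur, subvoxel shift, block-average downsampling)

   followed by a shear realignment that restores the true sample shape.
2. **Feature-based registration.** The sample is rotated about the
   vertical axis (8 views, 45° apart); beads or cell bodies are detected
   as difference-of-Gaussian blobs, matched between views with
   rotation-invariant descriptors plus a random-sample rigid consensus,
   and a rigid transform per view maps everything onto the reference view.
3. **Multiview deconvolution (MVD).** The registered views are fused by a
   weighted multiview Richardson–Lucy update with per-view PSFs `P_v` and
   content weights `w_v` (discarded deep-tissue content gets weight 0):

       ψ <- ψ * [ Σ_v w_v ((φ_v / (ψ ⊗ P_v)) ⊗ P_v*) ] / [ Σ_v w_v ⊗ P_v* ]

The methods vignette (`vignettes/svr-mvd-methods.Rmd`) documents the
models, parameters and numerical safeguards in detail.

## Worked example

The bead-characterization preset simulates eight views of ~500 nm beads
with the 4.2/12 µm PSF, 280 nm tilted steps and 4 × 4 × 2 enhancement
(native voxel 1.625 × 1.625 × 4.5 µm, reconstructed voxel reported as
0.41 µm), then runs the full pipeline:

```r
library(svrmvd)
run <- run_pipeline(pipeline_config(seed = 1), verbose = TRUE)
print(run)
```

prints (about 11 minutes on one CPU):

```
pipeline_run
  single-view SVR axial FWHM: 4.09 um
  fused lateral FWHM:         0.97 um
  fused axial FWHM:           1.01 um
  fused isotropy ratio:       1.05
  raw-volume MVD worst FWHM:  2.87 um
  bead recall:                1.00
```

Reading the numbers: the raw optics measure 4.2 µm lateral / 12 µm axial
on the same phantom. Single-view SVR sharpens the axial width to ≈4.1 µm;
fusing the eight raw (non-SVR) volumes alone reaches ≈2.9 µm in its worst
axis; the full SVR + MVD pipeline reaches ≈1 µm in every axis with an
axial/lateral ratio of ≈1 (isotropy), and every simulated bead is
recovered in the fused volume. Individual stages are exposed as ordinary
functions (`simulate_multiview()`, `run_svr()`, `detect_features()`,
`match_features()`, `fit_affine()`, `resample()`, `run_mvd()`,
`bead_resolution_report()`), and a thin command-line wrapper is installed
at `inst/cli/svrmvd`.

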