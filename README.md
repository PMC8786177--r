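# dbtdeblur

Limited-angle digital breast tomosynthesis (DBT) reconstructs a volume from
projections spanning only a narrow arc (±20°), which leaves a double wedge of
3D frequency space — the *missing cone* — unsampled and smears every
structure along the depth axis. `dbtdeblur` is an end-to-end, self-contained
R implementation of an in-silico study of this problem, aimed at image
reconstruction and deep-learning researchers in X-ray imaging:

* **Phantoms** — stochastic power-law breast textures (amplitude spectrum
  ∝ 1/f^{3/2}) thresholded to a target volumetric glandular fraction (VGF)
  with glandular/adipose attenuations 0.0802/0.0456 cm⁻¹ at 20 keV, plus
  optional spherical lesions (0.0844 cm⁻¹).
* **Projection** — exact Siddon ray tracing (C++) under one rotating
  cone-beam geometry (source 545 mm / detector 105 mm from the isocenter,
  450×450 detector at 0.125 mm): 41 views over ±20° for DBT, 360 views over
  the full circle for cone-beam CT (CBCT, the clean reference), with seeded
  Poisson counting noise.
* **Reconstruction** — FDK filtered backprojection with a Hanning-weighted
  ramp filter, plus empirical point-spread-function (PSF) characterization
  of the limited-angle system.
* **Two-phase deblurring CNN** — a 3D residual network (10 blocks, 40
  filters, receptive field 45) trained on 48³ patches with mean absolute
  error, followed by a coronal-plane U-Net (32 base filters, 4 levels,
  receptive field 140 — wide enough to cover the ~60-pixel coronal PSF)
  trained with MAE, adversarial (WGAN-GP, λ₁ = 0.001, PatchGAN critic) or
  perceptual (VGG-16-style extractor, λ₂ = 0.05) objectives. All network
  machinery (2D/3D convolution forward/backward, pooling, Adam, gradient
  penalty) is implemented in the package on BLAS-backed Rcpp primitives.
* **Evaluation** — per-plane mean 2D MSE, gradient RMSE, lesion
  contrast-to-noise ratio, and frequency-domain analysis of how the phases
  progressively refill the missing wedge.

The model being exercised is the linear image-formation view of limited-angle
reconstruction, `r = i ∗ p + n`: the DBT volume is the ideal image blurred by
the system PSF plus reconstruction noise, so restoration is a (spatially
structured) deconvolution problem that the two-phase network solves
coarse-to-fine — Phase 1 deblurs the 3D volume, Phase 2 sharpens the coronal
planes where the PSF is longest.

## Worked example

The full published protocol (899³ phantom cubes, 100 volume pairs, 100
epochs per phase) is a GPU-overnight workload; the package ships a reduced
`desk_profile()` (64×64×48 volumes, 16³ patches, scaled-down networks, 10
epochs) that runs the identical pipeline in a few minutes on one CPU:

```r
library(dbtdeblur)

# characterize the limited-angle PSF (unit impulse -> project -> FDK)
measure_psf(make_geometry("dbt"))
#> <psf_estimate> DBT -20..20 deg: depth extent 51 px, axial extent 11 px (5% threshold)

res <- run_two_phase_pipeline(desk_profile(seed = 1))
ref <- lapply(res$eval_pairs, `[[`, "cbct")
dbt <- lapply(res$eval_pairs, `[[`, "dbt")
round(1e5 * c(fdk   = mse_mean(ref, dbt, "axial")$mean,
              phase1 = mse_mean(ref, res$phase1_out, "axial")$mean,
              deblurred = mse_mean(ref, res$deblurred, "axial")$mean), 1)
#>       fdk    phase1 deblurred
#>     252.1      15.4      10.8
```

The three numbers are axial-plane mean squared errors (×10⁻⁵ cm⁻²) against
the CBCT reference on five held-out volumes: filtered backprojection alone,
after the Phase-1 3D network, and after the full two-phase model — a ~96 %
error reduction at desk scale, with the same monotone ordering the full-scale
study reports. `wedge_energy()` shows the same story in frequency space: the
missing-wedge spectral energy of the coronal slices rises from 0.0026 (DBT)
through 0.011 (Phase 1) to 0.054 (Phase 2), approaching the 0.268 of the
CBCT reference.

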