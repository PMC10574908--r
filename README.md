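# adaptpsf

Adaptive point-spread-function estimation and restoration for
dual-scintillator X-ray radiography.

## The problem

Indirect-conversion flat-panel detectors image through a scintillator whose
thickness trades sharpness against noise: thick layers absorb more X-rays
(less noise, more light spread, blurrier), thin layers are sharper but
noisier. When the same scene is available from two detectors of different
scintillator thickness, the blur difference between the pair can be measured
and undone. `adaptpsf` is for detector physicists and image-quality
engineers who want that workflow end to end, plus the simulation and
characterization tools needed to validate it without hardware.

The package models degradation as `g = PSF ⊗ f + N` with an isotropic
Gaussian PSF of width σ (pixels) and Poisson–Gaussian noise
`η²(x) = α·x + β²`. Its core estimator sweeps candidate widths σ, blurs the
sharp (thin-scintillator) image with each, scores it against the blurry
(thick-scintillator) image with SSIM and FSIM, and averages the two argmax
widths:

```
sigma_final = (argmax_σ SSIM + argmax_σ FSIM) / 2
```

The thick image is then deconvolved with that PSF, by default via
TV-regularized augmented-Lagrangian deconvolution

```
f* = argmin_f ‖PSF ⊗ f − g‖₂² + λ‖∇f‖₁ ,   λ = 0.01, tolerance 1e-4
```

which restores edges while suppressing the noise amplification of inverse
filtering. Wiener (`H*G/(|H|²+K)`) and Richardson–Lucy engines are included
for comparison, along with slit-based LSF/MTF characterization, flat-field
noise-level-function estimation, CNR and gradient-magnitude metrics, and a
cone-beam ray-traced simulator with three bundled detector profiles
(σ = 1.79/2.61/5.13 px, α = 0.37/0.29/0.08, β = 9.12/7.10/3.31 ADU).

## Worked example

Simulate a thin/thick pair of a resolution line chart, estimate the adaptive
PSF width, and restore the thick image:

```r
library(adaptpsf)

chart <- generate_line_chart(frequencies = c(0.8, 1.5, 2.5, 4))
thin  <- degrade_image(chart, detector_profile("detector1"), seed = 1)
thick <- degrade_image(chart, detector_profile("detector2"), seed = 2)

sw <- sweep_sigma(thin, thick, sigma_grid(0.2, 3, 0.1))
sw
#> Adaptive PSF sweep over sigma in [0.2, 3] (step 0.1):
#>   sigma_ssim  = 1.90 px
#>   sigma_fsim  = 1.90 px
#>   sigma_final = 1.90 px
```

Both metrics peak at 1.90 px — the width that makes the blurred thin image
most similar to the thick one, and (for these noise levels) right at the
Gaussian-semigroup prediction `sqrt(2.61² − 1.79²) ≈ 1.90` from the two
profile widths. `tidy(sw)` returns the score curves as a tibble and
`autoplot(sw)` plots them. Restoring the thick image with this PSF recovers
most of the sharpness gap to the thin detector:

```r
restored <- deconvolve_tv(thick, gaussian_psf_kernel(as.numeric(sw$sigma_final)),
                          tv_config())
sapply(list(thick = thick, restored = restored, thin = thin),
       function(x) gradient_magnitude(x)$score)
#>    thick restored     thin
#>   956.19  1193.95  1466.00
```

Gradient magnitude (mean Sobel response, a sharpness score) rises from 956
in the degraded thick image to 1194 after restoration, against 1466 for the
thin detector. Noise parameters are recovered from flat fields the same way:

```r
flats <- lapply(c(200, 1000, 3000), function(l)
  synthesize_noise(matrix(l, 256, 256), noise_model(0.37, 9.12), seed = l))
estimate_nlf(flats)
#> NLF estimate: alpha = 0.3668, beta = 9.173 ADU (760/768 blocks kept)
```

The full chain (`sweep → average → deconvolve → metrics`) is wrapped in
`run_pipeline(pipeline_config(...))`, and a command-line wrapper with
`simulate`, `estimate-sigma`, `deconvolve`, `metrics`, `mtf`, `nlf` and
`run` verbs lives in `inst/cli/adaptpsf.R`.

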