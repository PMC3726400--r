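# pexquant

Fully automatic quantification of **pseudoexfoliation syndrome (PEX)
severity** in visible-light anterior-segment eye photographs.

PEX deposits pathological fibrillar material between the pupil margin and
the outer iris border. Grading its extent by eye is subjective and poorly
reproducible; `pexquant` turns a single slit-lamp photograph into a number.

## Method

Given an RGB photograph the pipeline runs four automatic stages:

1. **Pre-processing** — 3×3 median filter per channel, per-channel
   normalization to [0, 1], gray conversion
   `L = 0.2989 R + 0.5870 G + 0.1140 B`.
2. **Pupil-centre localization** — a direction field `(L_m, L_θ)` is built
   from convolutions with a zero-mean oriented edge mask rotated over
   [0°, 180°); every strong-response pixel votes along the perpendicular
   line at `L_θ + 90°`, and the vote-accumulator maximum is the pupil
   centre `(m*, n*)` with pupil radius `r_z`.
3. **Polar contour extraction** — the gray image is resampled into
   `L(r, θ)` about the centre. The pupil contour `K_z(θ)` comes from Otsu
   binarization + polar-topology-aware hole filling + a periodic harmonic
   fit; the PEX rim `K_P(θ)` and iris border `K_I(θ)` from a radial active
   contour solved exactly by circular dynamic programming.
4. **Severity statistic** —

   `W_PEX = mean_θ [ (K_I(θ) − K_P(θ)) / K_I(θ) ] × 100%`

   together with a reliability flag `W_1/0` that fires when the PEX rim
   coincides with the pupil margin (rim not fully visible), and the
   relative error `δ = |W − W_ref| / W_ref × 100%` for comparisons against
   a reference reading.

The only instrument-specific parameter is the oriented-mask size (45 px for
a 1280×960 slit-lamp frame); it and the voting threshold scale automatically
with image resolution. Everything else is fixed by resolution-aware
defaults — see `vignette("pexquant-methods")`.

Because no public PEX image corpus exists, the package ships a synthetic
eye-phantom generator (`eye_phantom_spec()`, `render_phantom()`,
`phantom_suite()`) with exact ground-truth contours and configurable
Gaussian noise, plus an experiment harness (`noise_sweep()`,
`magnification_summary()`) for robustness studies.

## Worked example

```r
library(pexquant)

# a synthetic eye: pupil radius 33.6 px, iris 86.4 px, irregular PEX rim
# whose mean radius gives a true severity of 25%
spec <- eye_phantom_spec(
  size = c(192, 192), pupil_radius = 33.6, iris_radius = 86.4,
  pex_profile = random_pex_profile(7, 33.6, 86.4, n_harmonics = 3,
                                   amplitude = 0.35, mean_radius = 86.4 * 0.75),
  noise_var = 0.005, seed = 11)
ph <- render_phantom(spec)
ph$truth$w_pex_true
#> [1] 25

res <- measure_pex(ph$image)
res
#> PEX measurement: W_PEX = 24.97% (reliable)
#>   pupil centre (row, col) = (96, 96), r_z = 33.4 px
#>   valid angles: 360 / 360

delta_error(res$w_pex, ph$truth$w_pex_true)
#> [1] 0.1221375
```

`W_PEX = 24.97%` means the deposit band spans on average a quarter of the
radial distance from the centre out to the iris border; the reliability flag
confirms the rim was resolved everywhere, and the measurement misses the
ground truth by 0.12% relative error. For real photographs pass a file path:
`measure_pex("eye.jpg")`; `batch_measure()` processes directories into a CSV.

A thin command-line front end with `measure`, `batch`, `synth`,
`sweep-noise` and `summarize` subcommands is installed at
`system.file("cli", "pexquant.R", package = "pexquant")`.

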