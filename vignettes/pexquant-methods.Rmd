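---
title: "Measuring pseudoexfoliation severity: models, parameters and validation"
author: "pexquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pseudoexfoliation severity: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexquant)
```

## The measurement problem

Pseudoexfoliation syndrome (PEX) deposits fibrillar material on the anterior
segment of the eye. Under mydriasis, a slit lamp shows the deposit as a
grayish, irregular band between the pupil margin and the outer border of the
iris. Clinicians need a *quantitative, repeatable* severity measure, free of
operator interaction, so that disease progress can be compared across visits
and centres.

`pexquant` measures severity from a single visible-light photograph in four
stages:

1. **Pre-processing** — per-channel 3×3 median filtering, per-channel
   normalization to [0, 1], gray conversion with the standard luma weights
   (0.2989, 0.5870, 0.1140).
2. **Pupil-centre localization** — a *direction field* is computed by
   convolving the gray image with a zero-mean oriented step-edge mask rotated
   over [0°, 180°); each strong-response pixel casts votes along the line
   perpendicular to its edge orientation, and the vote maximum is the pupil
   centre. Perpendiculars of every concentric circular structure (pupil rim,
   deposit rim, iris border) pass through the same point, so the peak is
   sharp even when individual edges are noisy.
3. **Polar contour extraction** — the image is resampled about the centre
   into `L(r, θ)` (1 px radial, 1° angular step). The pupil contour `K_z(θ)`
   comes from Otsu binarization, morphological hole filling (specular
   highlights inside the pupil) and a periodic harmonic least-squares fit.
   The deposit rim `K_P(θ)` and iris border `K_I(θ)` come from a radial
   active contour solved exactly by circular dynamic programming.
4. **Severity statistic** —
   `W_PEX = mean over θ of (K_I(θ) − K_P(θ)) / K_I(θ) × 100%`,
   with a reliability flag that fires when the deposit rim was not resolved
   above the pupil margin.

## Notation and conventions

Images are indexed `[row m, column n]`; angles are degrees measured from the
image row axis, counter-clockwise, so the Cartesian point at radius `r` and
angle `θ` from centre `(m*, n*)` is `(m* − r sin θ, n* + r cos θ)`. Radial
contours are length-360 vectors on the 1° grid with per-angle validity flags
(angles whose samples fall outside the frame are excluded from all
statistics).

Defining `W_PEX` as a *mean* over angular samples deserves a note: a bare
sum over a dense angular grid would scale with the number of samples and
leave the percentage unit meaningless, while the mean is sampling-density
independent, bounded by [0, 100], and exactly invariant under a common
rescaling of all radii (hence independent of magnification). The reliability
rule is likewise stated positively: a measurement is *reliable* iff the
deposit rim stays strictly above the pupil margin
(`min over θ (K_P − K_z) > margin`) **and** the rim rests on visible edge
evidence at every angle. The second clause matters because a globally
optimal snake with an L1 smoothness penalty can *bridge* flat across an arc
where the rim has vanished (staying level costs no smoothness), so a purely
geometric coincidence test would miss some hidden-rim cases; a sustained arc
of near-zero edge strength along `K_P` is the direct signature of a rim that
is not fully visible, and `W_PEX` under-reports there.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mask_size` | 45 at 960 px frame height, scaled as `45·min(M,N)/960` | px | oriented-mask support; the single instrument parameter, fixed once per slit-lamp type |
| `theta_step` | 5 | degrees | direction-field angular sweep; smaller is slower, slightly more accurate |
| `vote_quantile` | `1 − 0.02·960/min(M,N)` | — | fraction of pixels allowed to vote; edge pixels scale like 1/size while area scales like 1/size², so the voting fraction grows as frames shrink |
| `r_min_frac`, `r_max_frac` | 0.02, 0.5 | of `min(M,N)` | admissible vote distances |
| `angular_step` | 1 | degrees | polar sampling; contours become length-360 vectors |
| `pupil_harmonics` | 4 | — | harmonic pairs in the periodic pupil fit |
| `smooth_pex`, `smooth_iris` | 2, 5 | energy/px | snake smoothness; the deposit rim is irregular, the iris border nearly circular |
| `pex_margin` | 3 | px | search floor above the pupil contour, so the snake cannot re-detect the pupil rim |
| `reliability_slack` | 1.5 | px | a snake within this distance of its floor is treated as pinned (rim not resolved) |
| `rim_strength_frac`, `rim_arc` | 0.2, 15 | —, degrees | rim-visibility requirement: any 15° arc of `K_P` resting on mean edge evidence below 0.2× the median rim strength flags the measurement unreliable |

All parameters except `mask_size` are automatic; `mask_size` and
`vote_quantile` scale with resolution, which is what makes the same
configuration work on full slit-lamp frames and on the smaller synthetic
images used for validation.

## Numerical choices

* **Oriented mask.** A `tanh` step profile across the orientation axis,
  tapered by a Gaussian envelope (σ = size/4.5), rotated by bilinear
  resampling and re-zero-meaned, so constant regions give exactly zero
  response. Responses are taken in absolute value; orientation lives in
  [0°, 180°) with ties resolved toward the smaller angle.
* **Voting.** Votes are cast in both directions along the perpendicular
  (the mask's polarity is not trusted), rasterized at 1 px steps. The
  accumulator is smoothed with a 5×5 box before the argmax
  (lexicographic tie-break) to suppress rasterization speckle.
* **Pupil radius.** All concentric eye structures vote through the centre,
  so the voter-distance distribution there is multimodal. The pupil radius
  is read from the *innermost* strong peak of the perimeter-normalized
  distance histogram (votes per unit circumference), not from the overall
  mean distance, which would land between the pupil and iris radii.
* **Pupil fit.** The raw per-column pupil edge is the end of the dark run
  starting at r = 0 after hole filling; the periodic fit is harmonic
  (a power-basis polynomial in θ would not close at 0°/360°). The fit is
  two-pass: residuals beyond 3·MAD (or 1.5 px) are trimmed and the fit
  repeated, because noise speckle fused with the pupil occasionally throws
  single-column gross outliers.
* **Radial snake.** Per-column edge energy is the negative signed radial
  gradient (sign fixed by the expected polarity of each boundary),
  normalized by its 95th in-band percentile; a small inward bias
  (`1e-4`/px) makes the contour collapse onto its band floor when no edge
  evidence exists, which is exactly the state the reliability flag detects.
  The circular optimum is computed exactly: a sweep over all candidate
  start radii with an O(states) L1 distance-transform per column, then a
  fixed-start backtrack. Sub-pixel refinement interpolates the energy
  parabola around the integer optimum (clamped to ±0.5 px).
* **Degenerate inputs.** Constant images produce no votes (error with a
  machine-readable class); collinear edges produce parallel perpendiculars
  and are flagged low-confidence; a missing dark region at the centre
  aborts with "pupil not found"; an empty snake band is a configuration
  error.

## The synthetic phantom generator

No public PEX image corpus exists, so validation uses a generator whose
geometry is known exactly: a dark pupil disc, an iris annulus with angular
fibre texture, a grayish deposit band whose outer rim is a band-limited
random harmonic profile `r_p(θ)`, a bright sclera, optional specular
highlight discs, and additive zero-mean Gaussian noise with variance up to
0.05 — the range over which robustness is swept. Default intensity levels
are pupil 0.05, iris 0.45, deposit 0.62, sclera 0.92, with ~1.2 px
anti-aliased boundaries; rendering is bitwise deterministic given the spec.

Textures modulate along the angle with only slowly varying radial factors:
early versions used radially periodic texture, which renders as concentric
rings — spurious edges *parallel to the true contours* that no real deposit
exhibits and that a radial snake will happily lock onto. Real iris fibres
and deposit flakes are angular structures.

The standard validation suite ([phantom_suite()]) holds 30 phantoms at
192×192 px with true severities uniformly spaced over 5–60% and three
pupil-size regimes (pupil diameter ≈ 60%, 35% and 10% of the frame height,
emulating high/medium/low magnification). Severity and pupil size cannot be
varied independently — a large pupil leaves no radial room for an extensive
deposit — so low severities pair with large pupils. Because the rim profile
is band-limited with zero-mean harmonics, the analytic truth is exactly
`w_true = (1 − mean(r_p)/r_i)·100`, and `compute_wpex()` applied to the
ground-truth contours reproduces it to 1e-6 (generator/metric closure).

What the phantoms deliberately do **not** model: eyelids and lashes,
off-axis illumination gradients, depth-of-field blur, deposits on the lens
inside the pupil aperture, and camera demosaicing artifacts. Passing the
phantom suite therefore demonstrates the geometric and statistical
correctness of the pipeline under controlled contrast and noise, not
clinical performance on arbitrary slit-lamp material.

## Validation experiments and problem sizes

Validation runs at desk scale: 192×192 phantoms (mask size 9) rather than
full 1280×960 frames (mask size 45), which keeps the complete suite and the
noise sweep in the span of minutes while exercising every stage at realistic
geometry ratios.

* **Accuracy**: on the 30-phantom suite with mild noise (σ² = 0.005), the
  mean relative severity error against ground truth (`delta_error`, in
  percent) is computed over reliable measurements and required to stay
  below 3%.
* **Noise robustness**: a sweep over σ² ∈ {0, 0.005, …, 0.05} with 3
  paired replicates per cell re-renders and re-measures a stratified
  six-phantom subset of the standard suite (two per pupil regime,
  severities spanning 5–60%); the mean error must grow with the noise
  level (endpoint comparison plus a rank-correlation trend check). The
  low-severity phantoms dominate this curve: their deposit band is only a
  few pixels wide, so contour jitter amplifies into relative error — the
  same fragility that noise causes on subtle clinical rims.
* **Optimality and oracles**: the snake's DP core is compared against
  exhaustive path enumeration on small grids; centre voting against a
  brute-force Hough circle transform and an algebraic circle fit; the
  median filter against a per-pixel sorted-neighborhood oracle; `W_PEX`
  against a per-angle accumulation loop.

## Known limitations

* The oriented-mask template and the strong-pixel voting rule are
  surrogates for instrument-calibrated equivalents; only their role (edge
  orientation estimation, centre evidence) is fixed, not their exact
  coefficients.
* The pupil-radius estimate degrades for very small pupils (≈ 10 px): the
  innermost histogram peak then carries few votes, and errors up to ~5%
  of the radius occur. The severity statistic does not depend on this
  estimate, so its accuracy is unaffected.
* Measurements on images whose iris border leaves the frame use only the
  valid angular range; severely decentred eyes reduce the usable range
  accordingly.
* `W_PEX` compares each measurement against the iris border at the *same*
  angle; strongly non-concentric pupils (post-surgical, trauma) violate the
  radial-contour assumption of one boundary sample per angle.

## Reproducing the headline number

`scripts/acceptance.R --seed S --out results/acceptance.json` regenerates
the 30-phantom suite from the given seed, measures every phantom with the
default configuration, and writes the mean relative severity error over
reliable measurements. The number is recomputed from scratch on every run;
nothing is cached.
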