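---
title: "Measuring trismus from phone photographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trismus from phone photographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trismometry)
```

## The measurement problem

Trismus — restricted mouth opening — is quantified as the interincisal
distance: the distance in millimetres between the incisal edges of the upper
and lower left central incisors. Measuring that distance on a photograph is
easy with any image tool; the hard part is *calibration*, converting pixels
to millimetres so that openings are absolute and comparable over time.
`trismometry` implements a frame-based calibration method for photographs
taken on patients' own phones, the six clinical scenarios in which it can be
deployed, and the statistics used to validate such a method.

Two calibration references are available:

* **A reference frame** — a hand-held card with a grey/white grid of known
  pitch and three colored discs (blue, red, green). The discs allow fully
  automatic ("macro") calibration; the grid supports a manual fallback.
* **The incisor width** — the horizontal distance between the distal edges
  of the two upper central incisors, a fixed anatomical landmark. Once
  known (from a frame-calibrated baseline photo, or from a clinical ruler),
  it calibrates later photos taken without the frame.

## Macro-calibration from the fiducial discs

`detect_discs()` thresholds the image in HSV space once per color label
(default hue windows blue 200–260°, green 90–150°, red 340–20° wrapping
zero; saturation ≥ 0.4, value ≥ 0.25), labels connected components, and
discards components smaller than `min_area_frac` (default 5×10⁻⁴ of the
image) or with isoperimetric circularity 4πA/P² below 0.6. The perimeter is
measured by Moore boundary tracing on the 8-connected component with
diagonal steps weighted √2; that convention scores a discretised disc at
about 0.93–0.95, well clear of the 0.6 cut, whereas an unweighted
crack-edge perimeter would put discs at π²/16 ≈ 0.62, uncomfortably close
to the threshold. Selection is deterministic (largest area, then higher
circularity, then smaller (y, x) centroid).

Two failure modes are first-class outcomes rather than crashes, because a
real batch contains them: no qualifying component for a color means the
frame was not (fully) in the picture (`frame_not_detected`), and two
similar-sized components of one color (areas within 25%) mean background
clutter is indistinguishable from the disc (`ambiguous_detection`).

`calibrate_from_discs()` converts the three pairwise centroid distances
into three scale estimates against the known disc separations. Their mean
gives `mm_per_px`; their worst relative deviation is the *residual*, which
flags tilt or perspective (default tolerance 3% — beyond it the photo
should be retaken, `calibration_inconsistent`). The sign of the disc
triangle's cross product detects mirroring (selfie cameras); mirroring
needs no correction, since distances are reflection-invariant, but is
reported. Anisotropy — the ratio of the singular values of the affine
transform fitted through the three point pairs — is a further diagnostic
for violations of the frontal, similarity-transform assumption. The model
is deliberately a single global scale: perspective rectification is out of
scope, and the diagnostics exist to detect when that assumption fails.

## The measurement scenarios

A study deploying the method chooses who photographs what:

| Scenario | Follow-up photo       | Calibration source                       |
|----------|-----------------------|------------------------------------------|
| M1       | portrait with frame   | macro (discs on the same photo) — gold standard |
| M2       | portrait, no frame    | incisor width from macro-calibrated baseline |
| M3       | portrait, no frame    | incisor width from clinical ruler        |
| M4       | selfie, no frame      | as M2                                    |
| M5       | selfie, no frame      | as M3                                    |
| M6       | portrait with frame   | manual two-point grid calibration        |

`run_scenario()` implements the matrix. Selfies are not a separate code
path: they differ from portraits only as scenes of lower quality (lower
resolution, heavier annotation jitter, mirrored), which is exactly how the
synthetic generator models them. Readings are rounded half-up to 0.01 mm at
the final step only; intermediate values keep full precision. Pipeline
failures on individual photos populate `excluded_reason`
(`frame_not_in_picture`, `background_noise`, `incisors_not_captured`,
`upload_error`) so a batch never aborts; automatic macro-calibration
failures from inconsistent disc geometry are filed under
`background_noise`, the closest of the four categories.

On noise-free synthetic scenes all six scenarios agree with the truth to
the 0.01 mm rounding — by construction, differences between scenarios arise
only from real-world noise (annotation jitter, resolution, ruler rounding).

## The synthetic scene generator

`render_frame_photo()` draws the grid and discs under a known similarity
transform (scale 2–20 px/mm, any rotation, optional mirroring), over a
white or cluttered background, with optional Gaussian pixel noise, and
returns the ground-truth disc positions alongside the image. An optional
anisotropic stretch produces negative tests for the similarity assumption.
`render_mouth_landmarks()` places the four anatomical landmarks at known
millimetre geometry with seeded Gaussian jitter emulating manual
annotation. The canvas is padded to at least 200 px on the short side so
that even 2 px/mm scenes produce workable images.

What the generator does *not* emulate — lens distortion, perspective
foreshortening, lighting gradients, lips occluding incisors, camera
compression — bounds what passing tests show: they validate the geometry,
the calibration arithmetic, the failure accounting and the statistics, not
robustness to every property of real photographs.

`simulate_measurement_study()` generates long-format measurement tables
under an additive error model: reading = truth + method bias +
participant-method component `b ~ N(0, σ²_b)` + reading-level noise
`e ~ N(0, σ²_w)`, with ruler readings rounded half-up to 1 mm. This is the
variance decomposition the repeated-measures limits-of-agreement analysis
assumes, so the statistics module's estimand is recoverable by
construction. Defaults describe a restricted-opening validation study:
50 participants × 2 fixed jaw positions, openings 25 ± 6 mm, incisor width
17 ± 1.2 mm, error components 0.6/0.6 mm, and per-method biases in the
regime reported for this family of methods (frame-calibrated scenarios
nearly unbiased; ruler-calibrated selfies overestimating by 0.8 mm; the
clinical ruler overestimating the opening by 1.72 mm and the width by
0.91 mm). A single integer seed drives all randomness.

## Agreement statistics

**ICC.** Reliability of repeated measurement of the same images uses the
single-measure, absolute-agreement ICC from a two-way random-effects model
(ICC(A,1)): with subjects × raters mean squares MSR, MSC, MSE,

$$\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \tfrac{k}{n}(MSC - MSE)}$$

with the Satterthwaite-based F confidence interval appropriate to this
form. Absolute agreement (not consistency) is the right choice because
repeated readings of one photograph must agree in value, not merely in
rank. A matrix with zero residual variance returns ICC 1 with a collapsed
interval; zero total variance is an error.

**Limits of agreement, repeated measures.** Differences are taken gold
standard minus comparator (negative mean ⇒ comparator overestimates). When
each subject contributes several occasions and the true opening varies
between them, a one-way ANOVA of the differences on subject gives MSW and
MSB; with the unbalanced-design average group size
$m_0 = (N - \sum m_i^2/N)/(n-1)$, the between-subject component is
$\hat\sigma^2_b = \max(0, (MSB - MSW)/m_0)$ (truncated at zero, so the
total SD never falls below √MSW), and

$$\mathrm{LoA} = \bar d \pm 1.96\,\sqrt{\hat\sigma^2_b + MSW}.$$

1.96 is used literally at the 95% level, matching Bland–Altman convention
and the planning arithmetic below. The limits' confidence intervals use
half-width 1.96·√(3/N)·SD (N = total observations) and the mean
difference's 1.96·√(σ̂²_b/n + MSW/N); the analysis behind such published
tables rarely states its CI construction, so these standard large-sample
choices are documented assumptions. `loa_independent()` is the sensitivity
analysis ignoring clustering; with one occasion per subject the two modes
coincide, and `loa_repeated()` falls back to it with a warning.

**Planning.** `icc_sample_size()` uses Bonett's precision approximation
$n = \lceil 8 z^2 (1-\rho)^2 (1+(k-1)\rho)^2 / (k(k-1)w^2) + 1 \rceil$
(w = full CI width); it was adopted because it reproduces the planning
numbers of the validation design this package targets (ρ = 0.9, k = 3,
half-width 0.05 → 42 images → 21 participants at two images each).
`loa_ci_halfwidth_factor()` gives the LoA precision multiplier z·√(3/n)
(0.34 at n = 100, whence 50 participants at two observations each).

## Numerical choices and problem sizes

* Rounding of readings: half-up, at 0.01 mm (ruler: 1 mm), final step only.
* Residual tolerance 3%, ambiguity band 25%, hue/saturation/value windows,
  area and circularity cuts: all defaults, all exposed as arguments.
* Detection winner selection and the simulator are fully deterministic
  given a seed; renders consume the current RNG stream only for noise and
  clutter.
* Negative variance components truncate at zero; degenerate inputs
  (coincident calibration points, constant ratings) raise classed errors.
* Test problem sizes were chosen to keep Monte-Carlo error well inside the
  asserted tolerances at reasonable runtime: 50 rendered scenes for the
  scale-recovery property; 200 replicates of 50 × 2 studies for sd_total
  recovery; 200 replicates of 42 × 3 matrices for ICC recovery; 100 000
  fresh differences for LoA coverage.

## Known limitations

* Single global scale: no lens-distortion or perspective model; violations
  are flagged (residual, anisotropy), not corrected.
* Landmarks are taken as given (manual annotation); the package does not
  localise incisal edges automatically.
* The error simulator draws Gaussian components with a common SD across
  methods; real methods differ in error variance as well as bias, which the
  per-method bias map captures only in location.

## A worked example

```{r example}
sim <- simulate_measurement_study(study_sim_params(seed = 42))
diffs <- differences_from_measurements(sim, gold = "M1", comparator = "ruler")
loa_repeated(diffs)
icc_sample_size(0.9, 3, 0.05)
```
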