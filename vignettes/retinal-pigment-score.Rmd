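---
title: "The Retinal Pigment Score: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Retinal Pigment Score: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpscore)
```

## The measurement model

The Retinal Pigment Score treats the colour of the retinal background —
the tissue between vessels, away from the optic disc — as a proxy for
choroidal/retinal-pigment-epithelium melanin. Three nuisance structures
must be excluded before the background colour is representative: the
vasculature (blood, not melanin), the optic disc (no pigment) and the
image border (black camera surround). The remaining pipeline is a chain of
deliberately simple, auditable colorimetric steps:

* **Border**: all pixels at or below the 0.5th percentile of the grayscale
  intensity distribution. With a standard circular field of view on a
  black surround, the surround occupies far more than 0.5% of pixels and
  sits at intensity 0, so the inclusive threshold recovers it exactly.
* **Exclusion mask**: the pixelwise union border ∪ vessels ∪ disc, dilated
  with the 8-connected 3×3 structuring element for
  `round(4·width/600)` iterations. Dilation buys a safety margin against
  segmentation undershoot; scaling the iteration count with image width
  keeps the margin a constant *physical* retinal distance across camera
  resolutions.
* **Representative colour**: the per-channel (marginal) median RGB over
  the background. The median over thousands of pixels is extremely robust
  to pixel-level noise and to small amounts of residual vessel
  contamination — a property that matters below.
* **Chromaticity**: the median colour is converted to CIELAB and only
  (a\*, b\*) is kept. CIELAB is designed to separate lightness from
  opponent chromatic axes, so dropping L\* removes (to first order) the
  effect of illumination intensity while retaining the red–brown colour
  signal that tracks pigmentation.
* **Scale**: a two-component PCA over the cohort's (a\*, b\*) points;
  each eye's score is the signed coordinate along the first eigenvector.
  Pigmentation moves a\* and b\* together (toward red-brown), so the first
  component captures the pigment axis and the second mostly residual
  nuisance.

Assumptions worth stating: the input is 8-bit sRGB without ICC-profile
correction; the background is large enough (the gradability gate enforces
≥10% of the frame) for a stable median; and pigmentation is the dominant
source of *chromatic* variation in the cohort used to fit the scale. The
score is cohort-relative — a projection, not an absolute pigment density —
which is why model persistence and transfer matter: applying one cohort's
fitted scale to another cohort scores both in the same units.

## Parameters and their defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `border_percentile` | 0.5 | % of pixels | matches the surround fraction of standard fields; inclusive threshold so ties are all flagged |
| `dilation_scale` / `reference_width` | 4 / 600 | iterations / px | four 1-px dilations at 600-px width; scales linearly with resolution |
| `connectivity` | 2 | — | the full 3×3 (8-neighbour) structuring element, the standard reading of connectivity-2 in 2-D morphology |
| grayscale weights | Rec.601 | — | no conversion rule is canonical for this step; Rec.601 luma is the common imaging default and is configurable |
| gradability floors | 10% area, 20% saturation, IQR 5 | — | conservative screens for empty background, overexposure and flat frames |
| ICC confidence | 0.95 | — | exact F-distribution bounds, deterministic (no bootstrap) |

Numerical conventions: the border percentile uses the linear-interpolation
quantile of the full pixel population; the iteration formula rounds
half-to-even; even-count medians take the *lower* median so the
representative colour is an actually occurring quantised value; PCA uses
the unbiased covariance (n−1); collinear point clouds are legal (second
eigenvalue 0) but a zero-variance cloud aborts. The PCA sign is fixed by
requiring scores to correlate positively with a\* (fallback b\*), so
greater RPS always means more pigmented; the orientation flag is stored in
the model file. Model JSON is written with 17 significant digits, which
round-trips IEEE doubles exactly: a loaded model projects bit-identically.

Two places expose deliberate alternatives: `background_chromaticity()` can
take medians per-pixel in Lab space instead of in RGB (sensitivity check;
identical on flat fields), and `rps_fit(..., variables = c("L","a","b"))`
fits the three-component variant used to quantify what discarding L\* buys.

## The synthetic generator

`synth_params()` / `generate_fundus()` render a circular field of view on
a black surround. A pigment parameter in [0, 1] drives the background
colour along a linear Lab ramp, L\* 75→35, a\* 10→30, b\* 25→45 — light
yellow-orange to dark red-brown, anchored at plausible fundus tones so
ground-truth ordering is unambiguous (the absolute anchors are synthetic
conventions, not measurements). A random-walk vessel tree (darker, redder)
and a bright disc on the nasal side are rendered with pixel-exact truth
masks. Two nuisance processes are modelled:

* **Illumination** is an additive L\*-plane: a per-image DC offset with SD
  `illumination_sd` plus a linear tilt at half that SD. This is exactly
  the dimension the (a,b)-only design discards, which makes the
  (a,b)-vs-(L,a,b) reliability comparison a meaningful stress test.
* **Acquisition noise** (`noise_sd`, 8-bit units) has two components of
  equal SD: i.i.d. per-pixel sensor noise, and a per-acquisition
  per-channel gain offset representing white-balance/exposure variation
  between captures. The split matters: a median over ~10³ background
  pixels reduces the effect of i.i.d. noise by ~√n, so pixel noise alone
  would leave repeat scores essentially identical at any plausible SD.
  What limits test–retest repeatability of a *spatial median* is the
  between-acquisition component, and the generator models it explicitly.

Default study conditions used by the validation experiments: 128×128
(or 64/96 px where many images are needed) rasters, vessel density 0.06,
disc radius 0.12 of the field radius, noise SD 2, pigment ~ Uniform(0, 1),
inter-eye pigment SD 0.02. Repeat acquisitions share the eye's pigment and
differ in rendering seed. Sizes were chosen so the full validation suite
runs in about a minute; the pipeline itself is resolution-aware through
the dilation rule.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: retinal texture (the background is flat, so
real-world median stability is *over*-estimated for i.i.d. noise and the
quality gate is rarely challenged), pathology (drusen, haemorrhage),
vignetting and chromatic aberration, camera-specific raw-RGB processing,
and the fact that a real eye keeps its vessel anatomy across repeats
(repeats here redraw the tree; with vessels excluded by masks either way,
this does not affect background chromaticity, but it means the baseline
segmenter's repeat behaviour is not a test of anatomical stability).

## Validation experiments

Every empirical claim in this vignette is computed by the test suite
(`tests/testthat/test-acceptance.R`) or by `scripts/acceptance.R`; none is
asserted from memory. In brief: the sRGB→CIELAB chain is checked against a
bundled independent reference grid (9³ colours) to 10⁻³; the morphology
and percentile rules are checked against brute-force oracles; luminance
shifts of ±20 L\* leave the score unchanged to 10⁻⁶ (quantisation-free
rendering) because only (a\*, b\*) enters the projection; a 200-image
uniform-pigment cohort is rank-recovered with Spearman ρ > 0.95; repeat
ICC is ≈1 at noise SD 1 and collapses below 0.5 at SD 40 (the gain-offset
component dominating); with illumination jitter of 10 L\*-units the
(a,b)-only score's inter-eye ICC clearly exceeds the (L,a,b) variant's;
and random 3×3 mask perturbations shift the median score by far less than
0.1 cohort-SD.

## Known limitations

* The score is cohort-relative and camera-relative; absolute cross-camera
  standardisation would require colorimetric calibration targets.
* The baseline segmenter is a classical heuristic intended for
  self-contained operation and testing; for clinical-grade masks, ingest
  segmentations from a dedicated tool via the manifest.
* The gradability gate is rule-based and conservative; it is a surrogate
  for learned quality classifiers and will admit some artefacts a trained
  model would reject.
* One-way ICC(1,1) is the only reliability model offered; designs with
  systematic rater/session effects would need two-way variants.
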