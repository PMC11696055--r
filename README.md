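# rpscore — Retinal Pigment Score from colour fundus photographs

`rpscore` quantifies the background pigmentation of the retina from an
ordinary colour fundus photograph as a single continuous number, the
**Retinal Pigment Score (RPS)**. Retinal pigmentation varies widely between
individuals and tracks systemic melanin biology; an objective, continuous,
illumination-robust measure of it is useful to ophthalmic epidemiologists,
to groups auditing retinal-imaging algorithms for performance differences
across pigmentation (a continuous alternative to coarse ethnicity labels),
and to anyone who needs a reproducible colorimetric phenotype from fundus
images.

## Method

For each image the pipeline:

1. detects the dark image border/surround as all pixels at or below the
   0.5th percentile of the grayscale (Rec.601 luma) intensity distribution;
2. forms the union of the vessel mask, optic-disc mask and border mask and
   dilates it with an 8-connected 3×3 structuring element for
   `round(4 · width / 600)` iterations — everything outside this exclusion
   mask is *retinal background*;
3. takes the per-channel median RGB colour of the background and converts
   it to CIELAB (sRGB, D65, 2° observer), keeping only the chromaticity
   pair (a\*, b\*) and discarding lightness L\*, which removes most of the
   effect of illumination;
4. fits a two-component PCA to the cohort's (a\*, b\*) points and projects
   each eye onto the eigenvector with the greatest eigenvalue:

   RPS = s · ⟨(a, b) − μ, **v**₁⟩,

   where μ is the cohort mean, **v**₁ the first eigenvector and
   s ∈ {+1, −1} an orientation fixed so that greater RPS means greater
   pigmentation (scores increase with a\*).

Vessel and disc masks can be ingested from any external segmentation tool,
or produced by the package's classical baseline segmenter (black top-hat
ridge detection for vessels; brightest compact component for the disc). A
rule-based gradability gate excludes images with too little background,
heavy saturation or no contrast. A fitted scale persists as JSON and can be
applied unchanged to a second cohort, putting both on one scale; one-way
intraclass correlation (ICC(1,1)) quantifies repeat-image and inter-eye
reliability; and a mask-perturbation analysis (random 3×3 erosion or
dilation of the vessel+disc mask) measures the score's robustness to
segmentation error. A synthetic fundus generator with exact ground-truth
masks and a known pigment parameter makes the whole pipeline testable with
no external data.

## Worked example

```r
library(rpscore)

co     <- simulate_cohort(40, eyes = c("right", "left"), seed = 2024,
                          base_params = synth_params(noise_sd = 2))
scores <- score_cohort(co)              # gradability, median RGB, CIELAB
model  <- fit_rps_from_scores(scores)   # cohort PCA scale
model
#> <rps_model on (a,b): n_fit=80, proportional eigenvalues 0.974/0.026, orientation -1>

scores <- apply_rps_model(scores, model)
scores[1:2, c("image_id", "median_R", "median_G", "median_B", "a", "b", "rps")]
#>         image_id median_R median_G median_B        a        b      rps
#> 1 p0001_right_r1      145       76       23 25.26922 41.89235 8.279504
#> 2  p0001_left_r1      152       81       26 25.62387 42.99743 9.303429

icc <- icc_oneway(pair_table(scores, "eyes"))
sprintf("inter-eye ICC %.3f (95%% CI %.3f, %.3f)", icc$icc, icc$ci_low, icc$ci_high)
#> "inter-eye ICC 0.978 (95% CI 0.959, 0.988)"
```

The first component carries 97% of the chromaticity variance, so the 1-D
projection loses little; the inter-eye ICC of 0.978 says two eyes of the
same (synthetic) participant receive nearly identical scores, as expected
when pigment is a person-level trait. Against the generator's ground truth
this cohort's RPS ranks pigment with Spearman ρ = 0.983.

A command-line interface with subcommands `simulate`, `score`, `fit`,
`apply`, `reliability` and `sensitivity` is installed at
`inst/cli/rps` (see `rps` with no arguments for usage).

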