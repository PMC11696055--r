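Package: rpscore
Title: Retinal Pigment Score from Colour Fundus Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a continuous, illumination-robust measure of background
    retinal pigmentation (the Retinal Pigment Score, RPS) from colour fundus
    photographs. The pipeline masks out vessels, the optic disc and the image
    border, takes the median colour of the remaining retinal background,
    converts it to CIELAB, and projects the (a*, b*) chromaticity pair onto
    the dominant axis of a cohort-level principal component analysis.
    Includes one-way intraclass correlation reliability analysis,
    cross-cohort model transfer on a persisted scale, mask-perturbation
    sensitivity analysis, and a synthetic fundus image generator with exact
    ground-truth masks for fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
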