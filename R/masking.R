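#' Masking parameters
#'
#' Parameters governing construction of the retinal-background exclusion
#' mask.
#'
#' @param border_percentile Percentile (in percent) of the grayscale
#'   distribution at or below which pixels are declared image border /
#'   surround. Default 0.5.
#' @param dilation_scale Multiplier in the dilation-iteration formula.
#'   Default 4.
#' @param reference_width Image width (pixels) at which `dilation_scale`
#'   iterations are applied; iterations scale linearly with actual width.
#'   Default 600.
#' @param connectivity Neighbourhood order of the structuring element;
#'   2 means the full 8-connected 3x3 element. Default 2.
#' @param grayscale_weights RGB weights for the grayscale conversion;
#'   default Rec.601 luma (0.299, 0.587, 0.114).
#' @return A list of class `masking_params`.
#' @export
masking_params <- function(border_percentile = 0.5, dilation_scale = 4,
                           reference_width = 600, connectivity = 2,
                           grayscale_weights = c(0.299, 0.587, 0.114)) {
  stopifnot(border_percentile > 0, border_percentile < 100,
            reference_width > 0, dilation_scale >= 0,
            connectivity %in% c(1, 2), length(grayscale_weights) == 3)
  structure(list(border_percentile = border_percentile,
                 dilation_scale = dilation_scale,
                 reference_width = reference_width,
                 connectivity = connectivity,
                 grayscale_weights = grayscale_weights),
            class = "masking_params")
}

structuring_element <- function(connectivity = 2) {
  if (connectivity == 2) matrix(1, 3, 3)
  else matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)  # 4-connected cross
}

#' Convert a fundus image to grayscale
#'
#' Rec.601 luma by default: `0.299 R + 0.587 G + 0.114 B` on 8-bit values.
#'
#' @param image A [fundus_image()] or an H x W x 3 array.
#' @param params A [masking_params()] (for the channel weights).
#' @return An H x W numeric matrix with values in \[0, 255\].
#' @export
to_grayscale <- function(image, params = masking_params()) {
  px <- if (inherits(image, "fundus_image")) image$pixels else image
  w <- params$grayscale_weights
  w[1] * px[, , 1] + w[2] * px[, , 2] + w[3] * px[, , 3]
}

#' Detect the image border / black surround
#'
#' Flags every pixel whose grayscale intensity is at or below the
#' `border_percentile`-th percentile (linear-interpolation percentile of the
#' full pixel population; the threshold is inclusive, so ties are all
#' flagged). On a constant image the percentile equals the constant and the
#' whole frame is flagged; the gradability gate then rejects such images.
#'
#' @param gray H x W grayscale matrix from [to_grayscale()].
#' @param params A [masking_params()].
#' @return A [binary_mask()] of kind `"border"`.
#' @export
detect_border <- function(gray, params = masking_params()) {
  thr <- stats::quantile(gray, probs = params$border_percentile / 100,
                         type = 7, names = FALSE)
  binary_mask((gray <= thr) * 1L, kind = "border", source = "derived")
}

#' Number of dilation iterations for a given image width
#'
#' `round(dilation_scale * width / reference_width)` with R's half-to-even
#' rounding; at the defaults this is `round(4 * width / 600)`.
#'
#' @param width Image width in pixels.
#' @param params A [masking_params()].
#' @return Non-negative integer iteration count.
#' @export
dilation_iterations <- function(width, params = masking_params()) {
  stopifnot(width > 0)
  as.integer(round(params$dilation_scale * width / params$reference_width))
}

#' One or more binary dilations / erosions
#'
#' Thin wrappers around EBImage grayscale-free binary morphology with an
#' explicit structuring element, applied `n` times.
#'
#' @param values 0/1 matrix or [binary_mask()].
#' @param n Number of iterations (0 returns the input unchanged).
#' @param kern Structuring element matrix; default full 3x3.
#' @return 0/1 integer matrix.
#' @export
binary_dilate <- function(values, n = 1L, kern = structuring_element(2)) {
  v <- mask_values(values)
  if (n == 0L || sum(v) == 0L) return(v + 0L)
  img <- EBImage::Image(v)
  for (i in seq_len(n)) img <- EBImage::dilate(img, kern)
  out <- EBImage::imageData(img)
  storage.mode(out) <- "integer"
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(values, n = 1L, kern = structuring_element(2)) {
  v <- mask_values(values)
  if (n == 0L) return(v + 0L)
  img <- EBImage::Image(v)
  for (i in seq_len(n)) img <- EBImage::erode(img, kern)
  out <- EBImage::imageData(img)
  storage.mode(out) <- "integer"
  out
}

#' Build the dilated exclusion mask
#'
#' Pixelwise union of the vessel, optic-disc and border masks, successively
#' dilated with the connectivity-2 (8-neighbour) 3x3 structuring element for
#' [dilation_iterations()] iterations. Everything outside this mask is
#' retinal background.
#'
#' @param vessel,disc,border Aligned [binary_mask()] objects or 0/1 matrices.
#' @param params A [masking_params()].
#' @param width Image width in pixels (drives the iteration count); defaults
#'   to the mask width.
#' @return A [binary_mask()] of kind `"combined"` with attribute
#'   `"iterations"`.
#' @export
build_exclusion_mask <- function(vessel, disc, border,
                                 params = masking_params(), width = NULL) {
  v <- mask_values(vessel); d <- mask_values(disc); b <- mask_values(border)
  check_alignment(d, dim(v), "disc mask")
  check_alignment(b, dim(v), "border mask")
  if (is.null(width)) width <- ncol(v)
  iters <- dilation_iterations(width, params)
  u <- ((v + d + b) > 0) * 1L
  out <- binary_dilate(u, n = iters,
                       kern = structuring_element(params$connectivity))
  m <- binary_mask(out, kind = "combined", source = "derived")
  attr(m, "iterations") <- iters
  m
}

#' Derive the retinal-background mask
#'
#' Complement of [build_exclusion_mask()]: all pixels not contained in the
#' dilated vessel/disc/border mask.
#'
#' @param image A [fundus_image()].
#' @param vessel,disc Binary masks aligned to the image.
#' @param params A [masking_params()].
#' @param border Optional precomputed border mask; detected from the image
#'   when `NULL`.
#' @return A [binary_mask()] of kind `"retinal_background"` with attributes
#'   `"n_pixels"` and `"iterations"`.
#' @export
retinal_background_mask <- function(image, vessel, disc,
                                    params = masking_params(),
                                    border = NULL) {
  if (is.null(border)) {
    border <- detect_border(to_grayscale(image, params), params)
  }
  excl <- build_exclusion_mask(vessel, disc, border, params,
                               width = image$width)
  bg <- 1L - excl$values
  n <- sum(bg)
  if (n == 0L) {
    stop("rps_gradability_error: exclusion mask covers the entire image (",
         image$image_id, ")", call. = FALSE)
  }
  m <- binary_mask(bg, kind = "retinal_background", source = "derived")
  attr(m, "n_pixels") <- n
  attr(m, "iterations") <- attr(excl, "iterations")
  m
}

#' Randomly perturb a segmentation mask
#'
#' Sensitivity-analysis operator: with a seeded generator, choose binary
#' erosion or binary dilation with probability 1/2 each and apply one
#' iteration with a full 3x3 kernel.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param seed Integer seed; the same seed always yields the same choice.
#' @return A [binary_mask()] of the same kind with attribute `"operation"`
#'   (`"erosion"` or `"dilation"`).
#' @export
perturb_mask <- function(mask, seed) {
  op <- with_local_seed(seed, {
    if (stats::runif(1) < 0.5) "erosion" else "dilation"
  })
  kern <- matrix(1, 3, 3)
  v <- mask_values(mask)
  out <- if (op == "erosion") binary_erode(v, 1L, kern)
         else binary_dilate(v, 1L, kern)
  kind <- if (inherits(mask, "binary_mask")) mask$kind else "combined"
  m <- binary_mask(out, kind = kind, source = "derived")
  attr(m, "operation") <- op
  m
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Classical baseline vessel and disc segmentation
#'
#' Deterministic heuristic segmenter used when no precomputed masks are
#' supplied: vessels are detected as dark ridges with a morphological black
#' top-hat thresholded by Otsu's rule inside the field of view; the optic
#' disc as the largest compact bright component near the intensity maximum,
#' regularised by a morphological opening. Intended for self-contained
#' pipelines and tests, not as a clinical-grade segmenter.
#'
#' @param image A [fundus_image()].
#' @param params A [masking_params()].
#' @return A list with elements `vessel` and `disc`, both [binary_mask()]
#'   objects with `source = "baseline_segmenter"`.
#' @export
segment_baseline <- function(image, params = masking_params()) {
  g <- to_grayscale(image, params)
  border <- detect_border(g, params)$values
  field <- border == 0L
  h <- nrow(g); w <- ncol(g)
  empty <- matrix(0L, h, w)
  if (!any(field)) {
    return(list(vessel = binary_mask(empty, "vessel", "baseline_segmenter"),
                disc = binary_mask(empty, "disc", "baseline_segmenter")))
  }
  gi <- EBImage::Image(g / 255)

  # vessels: black top-hat picks dark curvilinear structure
  brush_r <- max(5L, as.integer(round(w / 60)))
  if (brush_r %% 2 == 0) brush_r <- brush_r + 1L
  closed <- EBImage::closing(gi, EBImage::makeBrush(brush_r, shape = "disc"))
  tophat <- EBImage::imageData(closed) - EBImage::imageData(gi)
  tophat[!field] <- 0
  vessel <- empty
  tvals <- tophat[field]
  if (max(tvals) > 1e-6) {
    thr <- otsu_threshold(tvals)
    # require meaningful contrast so a vessel-free field stays empty
    thr <- max(thr, 0.05)
    vessel <- (tophat > thr & field) * 1L
  }

  # disc: brightest compact region; threshold halfway between the field's
  # median and maximum so a flat background never floods the candidate set
  disc <- empty
  qhi <- (stats::median(g[field]) + max(g[field])) / 2
  cand <- (g >= qhi & field) * 1
  cand <- EBImage::imageData(EBImage::opening(
    EBImage::Image(cand), EBImage::makeBrush(5, shape = "disc")))
  lab <- EBImage::bwlabel(EBImage::Image(cand))
  labv <- EBImage::imageData(lab)
  if (max(labv) >= 1) {
    sizes <- tabulate(labv[labv > 0])
    disc <- (labv == which.max(sizes)) * 1L
    # fill and regularise the chosen component
    r <- max(3L, as.integer(round(sqrt(max(sizes) / pi) / 2)))
    disc <- binary_erode(binary_dilate(disc, 1L, EBImage::makeBrush(2 * r + 1, "disc")),
                         1L, EBImage::makeBrush(2 * r + 1, "disc"))
  }
  list(vessel = binary_mask(vessel, "vessel", "baseline_segmenter"),
       disc = binary_mask(disc * 1L, "disc", "baseline_segmenter"))
}

# Otsu's threshold on a numeric vector in [0, 1]
otsu_threshold <- function(x, breaks = 256L) {
  h <- tabulate(pmin(pmax(as.integer(x * (breaks - 1L)) + 1L, 1L), breaks),
                breaks)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(breaks))
  mu_t <- mu[breaks]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 0.5) / (breaks - 1L)
}

#' Rule-based image gradability gate
#'
#' Conservative quality screen applied before scoring. An image fails when
#' any of the following holds: the retinal background covers less than
#' `min_background_frac` of the field of view, more than
#' `max_saturated_frac` of background pixels are saturated (>= 250 in any
#' channel), or the grayscale interquartile range falls below `min_iqr`
#' (flat, contrast-less frames).
#'
#' @param image A [fundus_image()].
#' @param background_mask The [retinal_background_mask()] of the image.
#' @param min_background_frac Minimum background area as a fraction of the
#'   frame. Default 0.10.
#' @param max_saturated_frac Maximum tolerated fraction of saturated
#'   background pixels. Default 0.20.
#' @param min_iqr Minimum grayscale interquartile range (8-bit units).
#'   Default 5.
#' @param params A [masking_params()].
#' @return A list with `pass` (logical) and `reasons` (character vector).
#' @export
assess_gradability <- function(image, background_mask,
                               min_background_frac = 0.10,
                               max_saturated_frac = 0.20,
                               min_iqr = 5,
                               params = masking_params()) {
  reasons <- character(0)
  bg <- mask_values(background_mask)
  n_bg <- sum(bg)
  n_total <- length(bg)
  if (n_bg < min_background_frac * n_total) {
    reasons <- c(reasons, "empty background")
  }
  # with an empty background the saturation check falls back to the frame
  idx <- if (n_bg > 0) bg == 1L else rep(TRUE, n_total)
  sat <- (image$pixels[, , 1][idx] >= 250) |
         (image$pixels[, , 2][idx] >= 250) |
         (image$pixels[, , 3][idx] >= 250)
  if (mean(sat) > max_saturated_frac) reasons <- c(reasons, "saturation")
  g <- to_grayscale(image, params)
  if (stats::IQR(g) < min_iqr) reasons <- c(reasons, "low contrast")
  list(pass = length(reasons) == 0, reasons = reasons)
}
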