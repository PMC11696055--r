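# sRGB <-> CIELAB conversion, D65 white point, 2 degree standard observer.
# Constants follow the ITU-R BT.709 primaries as published for sRGB; the
# white point is (0.95047, 1, 1.08883).
SRGB_TO_XYZ <- matrix(c(0.412453, 0.357580, 0.180423,
                        0.212671, 0.715160, 0.072169,
                        0.019334, 0.119193, 0.950227),
                      nrow = 3, byrow = TRUE)
XYZ_TO_SRGB <- solve(SRGB_TO_XYZ)
D65_WHITE <- c(0.95047, 1.00000, 1.08883)

srgb_decode <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

srgb_encode <- function(lin) {
  lin <- pmax(lin, 0)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

lab_f_inv <- function(ft) {
  delta <- 6 / 29
  ifelse(ft > delta, ft^3, 3 * delta^2 * (ft - 4 / 29))
}

#' Convert sRGB colours to CIELAB
#'
#' Standard chain: IEC 61966-2-1 piecewise linearisation, linear RGB to CIE
#' XYZ under D65 / 2-degree observer, then the CIELAB f-function with the
#' 6/29 cube-root threshold.
#'
#' @param rgb Numeric vector of length 3, or an n x 3 matrix, of 8-bit
#'   channel values in \[0, 255\].
#' @return A matrix (or named vector for a single colour) with columns
#'   `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  single <- is.null(dim(rgb))
  m <- if (single) matrix(rgb, nrow = 1) else as.matrix(rgb)
  stopifnot(ncol(m) == 3)
  lin <- srgb_decode(m / 255)
  xyz <- lin %*% t(SRGB_TO_XYZ)
  fx <- lab_f(sweep(xyz, 2, D65_WHITE, "/"))
  L <- 116 * fx[, 2] - 16
  a <- 500 * (fx[, 1] - fx[, 2])
  b <- 200 * (fx[, 2] - fx[, 3])
  out <- cbind(L = L, a = a, b = b)
  if (single) out[1, ] else out
}

#' Convert CIELAB colours to sRGB
#'
#' Inverse of [srgb_to_lab()]; out-of-gamut results are clipped to
#' \[0, 255\].
#'
#' @param lab Numeric vector of length 3, or an n x 3 matrix, with columns
#'   `L`, `a`, `b`.
#' @return 8-bit channel values (continuous; not rounded) with columns
#'   `R`, `G`, `B`.
#' @export
lab_to_srgb <- function(lab) {
  single <- is.null(dim(lab))
  m <- if (single) matrix(lab, nrow = 1) else as.matrix(lab)
  stopifnot(ncol(m) == 3)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(lab_f_inv(fx), lab_f_inv(fy), lab_f_inv(fz))
  xyz <- sweep(xyz, 2, D65_WHITE, "*")
  lin <- xyz %*% t(XYZ_TO_SRGB)
  out <- pmin(pmax(srgb_encode(lin) * 255, 0), 255)
  colnames(out) <- c("R", "G", "B")
  if (single) out[1, ] else out
}

#' Alias for converting one 8-bit RGB triple to CIELAB
#'
#' @param rgb Length-3 vector of channel values in \[0, 255\].
#' @return Named vector `c(L, a, b)`.
#' @export
rgb_to_lab <- function(rgb) {
  stopifnot(length(rgb) == 3, all(rgb >= 0), all(rgb <= 255))
  srgb_to_lab(rgb)
}

# lower median: the floor((n+1)/2)-th order statistic, so the representative
# value is an actually occurring quantised intensity
lower_median <- function(x) {
  n <- length(x)
  sort(x, partial = (n + 1L) %/% 2L)[(n + 1L) %/% 2L]
}

#' Median RGB of the retinal background
#'
#' Per-channel (marginal) median over the pixels of the background mask.
#' Even-sized samples use the lower median, keeping each channel an actually
#' occurring 8-bit value.
#'
#' @param image A [fundus_image()].
#' @param background_mask A [binary_mask()] aligned to the image.
#' @return Named numeric vector `c(R, G, B)`.
#' @export
median_rgb <- function(image, background_mask) {
  bg <- mask_values(background_mask)
  check_alignment(bg, dim(image$pixels)[1:2], "background mask")
  idx <- bg == 1L
  if (!any(idx)) {
    stop("rps_gradability_error: empty background mask for image ",
         image$image_id, call. = FALSE)
  }
  c(R = lower_median(image$pixels[, , 1][idx]),
    G = lower_median(image$pixels[, , 2][idx]),
    B = lower_median(image$pixels[, , 3][idx]))
}

#' Extract the chromaticity pair from a CIELAB triple
#'
#' Retains only the opponent axes (a*, b*), discarding lightness L* — the
#' step that makes the score robust to illumination differences.
#'
#' @param lab Named vector with elements `L`, `a`, `b` (as from
#'   [rgb_to_lab()]).
#' @return Named vector `c(a, b)`.
#' @export
extract_chromaticity <- function(lab) {
  stopifnot(all(c("a", "b") %in% names(lab)), all(is.finite(lab)))
  c(a = unname(lab[["a"]]), b = unname(lab[["b"]]))
}

#' Representative background chromaticity of one image
#'
#' The default (`method = "median_rgb"`) takes the per-channel median RGB of
#' the background and converts that single colour to CIELAB. The alternative
#' (`method = "median_lab"`) converts every background pixel first and takes
#' per-channel medians in Lab space; it is provided for sensitivity checks.
#'
#' @param image A [fundus_image()].
#' @param background_mask A [binary_mask()].
#' @param method `"median_rgb"` (default) or `"median_lab"`.
#' @return List with `rgb` (NA triple for `"median_lab"`), `lab` and
#'   `chroma` components.
#' @export
background_chromaticity <- function(image, background_mask,
                                    method = c("median_rgb", "median_lab")) {
  method <- match.arg(method)
  if (method == "median_rgb") {
    med <- median_rgb(image, background_mask)
    lab <- rgb_to_lab(med)
  } else {
    bg <- mask_values(background_mask)
    idx <- bg == 1L
    if (!any(idx)) {
      stop("rps_gradability_error: empty background mask for image ",
           image$image_id, call. = FALSE)
    }
    px <- cbind(image$pixels[, , 1][idx], image$pixels[, , 2][idx],
                image$pixels[, , 3][idx])
    labs <- srgb_to_lab(px)
    lab <- c(L = lower_median(labs[, 1]), a = lower_median(labs[, 2]),
             b = lower_median(labs[, 3]))
    med <- c(R = NA_real_, G = NA_real_, B = NA_real_)
  }
  list(rgb = med, lab = lab, chroma = extract_chromaticity(lab))
}
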