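MODEL_FORMAT_VERSION <- "1.0"

#' Construct a fundus image object
#'
#' A `fundus_image` bundles an 8-bit RGB raster with the identity metadata
#' (participant, eye, acquisition index) that the scoring and reliability
#' machinery needs. Pixels are stored row-major, origin at the top-left,
#' as an H x W x 3 integer array with values in 0..255.
#'
#' @param pixels H x W x 3 numeric array of 8-bit intensities (sRGB).
#' @param image_id Character scalar identifying the image.
#' @param participant_id Character scalar identifying the participant.
#' @param eye `"right"` or `"left"`.
#' @param repeat_index Integer >= 1, the acquisition index for repeat images.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, image_id = "img", participant_id = "p1",
                         eye = c("right", "left"), repeat_index = 1L) {
  eye <- match.arg(eye)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("rps_format_error: pixels must be an H x W x 3 array, got ",
         paste(dim(pixels), collapse = "x"), call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 64L || d[2] < 64L) {
    stop("rps_format_error: image dimensions must be at least 64x64, got ",
         d[1], "x", d[2], call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("rps_format_error: pixel values must lie in [0, 255]", call. = FALSE)
  }
  # 8-bit rasters are stored as integers; continuous-valued synthetic
  # rasters (quantisation-free experiments) stay double
  if (all(pixels == round(pixels))) storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, height = d[1], width = d[2],
         image_id = as.character(image_id),
         participant_id = as.character(participant_id),
         eye = eye, repeat_index = as.integer(repeat_index)),
    class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image %s: %dx%d, participant %s, %s eye, repeat %d>\n",
              x$image_id, x$height, x$width, x$participant_id, x$eye,
              x$repeat_index))
  invisible(x)
}

#' Construct a binary mask aligned to an image
#'
#' @param values H x W matrix of 0/1 (logical or numeric).
#' @param kind One of `"vessel"`, `"disc"`, `"border"`, `"combined"`,
#'   `"retinal_background"`.
#' @param source Provenance: `"ingested"`, `"baseline_segmenter"` or
#'   `"derived"`.
#' @return An object of class `binary_mask` whose `values` are an integer
#'   0/1 matrix.
#' @export
binary_mask <- function(values,
                        kind = c("vessel", "disc", "border", "combined",
                                 "retinal_background"),
                        source = c("derived", "ingested",
                                   "baseline_segmenter")) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  if (!is.matrix(values)) stop("rps_format_error: mask must be a matrix",
                               call. = FALSE)
  v <- values
  if (is.logical(v)) v <- v * 1L
  if (anyNA(v) || !all(v %in% c(0L, 1L))) {
    stop("rps_format_error: mask values must be strictly binary",
         call. = FALSE)
  }
  storage.mode(v) <- "integer"
  structure(list(values = v, kind = kind, source = source),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s (%s): %dx%d, %d foreground px>\n",
              x$kind, x$source, nrow(x$values), ncol(x$values),
              sum(x$values)))
  invisible(x)
}

mask_values <- function(m) if (inherits(m, "binary_mask")) m$values else m

check_alignment <- function(values, expected_shape, what = "mask") {
  got <- dim(values)[1:2]
  if (!identical(as.integer(got), as.integer(expected_shape))) {
    stop(sprintf("rps_alignment_error: %s shape %dx%d does not match expected %dx%d",
                 what, got[1], got[2], expected_shape[1], expected_shape[2]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a colour fundus photograph
#'
#' Reads an 8-bit RGB PNG or JPEG into a [fundus_image()]. Identity metadata
#' comes from the caller (typically a manifest row), never from the filename.
#'
#' @param path Path to a 3-channel PNG or JPEG file.
#' @inheritParams fundus_image
#' @return A [fundus_image()].
#' @export
read_fundus_image <- function(path, image_id = basename(path),
                              participant_id = "p1",
                              eye = c("right", "left"), repeat_index = 1L) {
  if (!file.exists(path)) {
    stop("rps_io_error: no such file: ", path, call. = FALSE)
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("rps_io_error: cannot read ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) != 3L || dim(a)[3] < 3L) {
    nch <- if (length(dim(a)) == 2L) 1L else dim(a)[3]
    stop("rps_format_error: expected a 3-channel RGB image, got ", nch,
         " channel(s) in ", path, call. = FALSE)
  }
  # EBImage stores width x height x channel in [0, 1]; drop any alpha plane
  px <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  px <- round(px * 255)
  fundus_image(px, image_id = image_id, participant_id = participant_id,
               eye = eye, repeat_index = repeat_index)
}

#' Write a fundus image to a PNG file
#'
#' @param image A [fundus_image()].
#' @param path Output path (`.png`).
#' @export
write_fundus_image <- function(image, path) {
  a <- aperm(image$pixels, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Read a binary segmentation mask
#'
#' Any nonzero pixel is treated as foreground, which tolerates antialiased
#' exports with intermediate grey values.
#'
#' @param path Path to a PNG mask file.
#' @param expected_shape Integer pair `c(height, width)` the mask must match;
#'   no implicit resizing is performed.
#' @param kind Mask kind, see [binary_mask()].
#' @return A [binary_mask()] with `source = "ingested"`.
#' @export
read_mask <- function(path, expected_shape, kind = "vessel") {
  if (!file.exists(path)) {
    stop("rps_io_error: no such file: ", path, call. = FALSE)
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("rps_io_error: cannot read ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  v <- t(a)          # width x height -> row-major height x width
  check_alignment(v, expected_shape, what = paste0("mask ", basename(path)))
  binary_mask((v > 0) * 1L, kind = kind, source = "ingested")
}

#' Write a binary mask as an 8-bit PNG (0/255 semantics)
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param path Output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  v <- mask_values(mask)
  EBImage::writeImage(EBImage::Image(t(v * 1.0)), path)
  invisible(path)
}

MANIFEST_REQUIRED <- c("image_path", "participant_id", "eye", "repeat_index")

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `image_path`, `participant_id`, `eye`,
#' `repeat_index` and optional `vessel_mask_path` / `disc_mask_path`. Relative
#' paths are resolved against the manifest's own directory. Load order is
#' preserved.
#'
#' @param path Path to the manifest CSV.
#' @param check_paths Verify that every referenced file exists (default TRUE).
#' @return A data frame, one row per image, with resolved absolute paths.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    stop("rps_io_error: no such manifest: ", path, call. = FALSE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_REQUIRED, names(m))
  if (length(missing) > 0) {
    stop("rps_format_error: manifest missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(m$eye %in% c("right", "left"))) {
    stop("rps_format_error: manifest eye column must be 'right' or 'left'",
         call. = FALSE)
  }
  key <- paste(m$participant_id, m$eye, m$repeat_index)
  if (anyDuplicated(key)) {
    stop("rps_format_error: duplicate (participant_id, eye, repeat_index) in manifest",
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "", NA_character_,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  m$image_path <- resolve(m$image_path)
  for (col in c("vessel_mask_path", "disc_mask_path")) {
    if (col %in% names(m)) m[[col]] <- resolve(m[[col]]) else m[[col]] <- NA_character_
  }
  if (check_paths) {
    paths <- c(m$image_path, stats::na.omit(m$vessel_mask_path),
               stats::na.omit(m$disc_mask_path))
    bad <- paths[!file.exists(paths)]
    if (length(bad) > 0) {
      stop("rps_io_error: manifest references missing file(s): ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
  }
  m
}

SCORE_COLUMNS <- c("image_id", "participant_id", "eye", "repeat_index",
                   "gradable", "reasons", "median_R", "median_G", "median_B",
                   "L", "a", "b", "rps")

#' Write per-image scores to CSV
#'
#' One row per image with the audit trail the pipeline produces: gradability,
#' median RGB of the retinal background, its CIELAB triple, and (when a model
#' was applied) the RPS. Non-finite scores of ungradable images are written
#' as empty cells.
#'
#' @param records Data frame of scored images (see [score_cohort()]).
#' @param path Output CSV path.
#' @export
write_scores <- function(records, path) {
  if (nrow(records) == 0) {
    records <- as.data.frame(stats::setNames(
      replicate(length(SCORE_COLUMNS), character(0), simplify = FALSE),
      SCORE_COLUMNS))
  } else {
    for (col in setdiff(SCORE_COLUMNS, names(records))) records[[col]] <- NA
    records <- records[, SCORE_COLUMNS]
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a scores CSV written by [write_scores()]
#'
#' @param path Path to the scores CSV.
#' @return Data frame with the standard score columns.
#' @export
read_scores <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image_id = "character",
                                      participant_id = "character"))
  missing <- setdiff(SCORE_COLUMNS, names(s))
  if (length(missing) > 0) {
    stop("rps_format_error: scores file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  s$gradable <- as.logical(s$gradable)
  s
}

#' Persist a fitted RPS model as JSON
#'
#' The file stores the chromaticity mean, eigenvector matrix, eigenvalues,
#' orientation flag and an explicit `format_version`, so a scale fitted on
#' one cohort can be applied unchanged to another. Loading reproduces
#' projections exactly (values round-trip through full-precision decimal
#' strings).
#'
#' @param model An [rps_fit()] model.
#' @param path Output path (`.json`).
#' @export
save_rps_model <- function(model, path) {
  stopifnot(inherits(model, "rps_model"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    variables = model$variables,
    mean = model$mean,
    eigenvectors = model$eigenvectors,   # rows = components
    eigenvalues = model$eigenvalues,
    proportional_eigenvalues = model$proportional_eigenvalues,
    orientation = model$orientation,
    n_fit = model$n_fit)
  # 17 significant digits round-trip IEEE doubles exactly, so loaded models
  # project bit-identically to the fitted one
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a persisted RPS model
#'
#' Refuses (rather than silently coerces) files with an unknown
#' `format_version`, because cross-cohort transfer depends on the stored
#' scale being interpreted exactly as written.
#'
#' @param path Path to a model JSON file written by [save_rps_model()].
#' @return An `rps_model` object.
#' @export
load_rps_model <- function(path) {
  if (!file.exists(path)) {
    stop("rps_io_error: no such model file: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version)) {
    stop("rps_schema_error: model file has no format_version", call. = FALSE)
  }
  if (!identical(as.character(obj$format_version), MODEL_FORMAT_VERSION)) {
    stop("rps_version_error: model format_version '", obj$format_version,
         "' is not supported (expected '", MODEL_FORMAT_VERSION, "')",
         call. = FALSE)
  }
  required <- c("mean", "eigenvectors", "eigenvalues",
                "proportional_eigenvalues", "orientation", "n_fit")
  missing <- required[vapply(required, function(f) is.null(obj[[f]]), TRUE)]
  if (length(missing) > 0) {
    stop("rps_schema_error: model file missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev <- obj$eigenvectors
  if (!is.matrix(ev)) ev <- do.call(rbind, ev)
  vars <- obj$variables
  if (is.null(vars)) vars <- c("a", "b")
  m <- structure(list(
    variables = vars,
    mean = stats::setNames(as.numeric(obj$mean), vars),
    eigenvectors = matrix(as.numeric(ev), nrow = nrow(ev)),
    eigenvalues = as.numeric(obj$eigenvalues),
    proportional_eigenvalues = as.numeric(obj$proportional_eigenvalues),
    orientation = as.numeric(obj$orientation),
    n_fit = as.integer(obj$n_fit)), class = "rps_model")
  validate_rps_model(m)
  m
}
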