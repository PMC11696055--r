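#' Score a single fundus image
#'
#' Runs the full per-image pipeline: border detection, exclusion-mask
#' construction from the vessel and disc masks, gradability assessment,
#' median background colour, CIELAB conversion and — when a model is
#' supplied — projection to the RPS. Ungradable images yield a row with
#' `gradable = FALSE` and NA colour fields instead of an error.
#'
#' @param image A [fundus_image()].
#' @param vessel,disc Binary masks aligned to the image (truth, ingested or
#'   from [segment_baseline()]).
#' @param params A [masking_params()].
#' @param model Optional [rps_fit()] model; adds an `rps` column.
#' @param chroma_method Passed to [background_chromaticity()].
#' @return One-row data frame with the standard score columns.
#' @export
score_image <- function(image, vessel, disc, params = masking_params(),
                        model = NULL,
                        chroma_method = c("median_rgb", "median_lab")) {
  chroma_method <- match.arg(chroma_method)
  row <- data.frame(image_id = image$image_id,
                    participant_id = image$participant_id,
                    eye = image$eye, repeat_index = image$repeat_index,
                    gradable = FALSE, reasons = "",
                    median_R = NA_real_, median_G = NA_real_,
                    median_B = NA_real_,
                    L = NA_real_, a = NA_real_, b = NA_real_,
                    rps = NA_real_, stringsAsFactors = FALSE)
  bg <- tryCatch(retinal_background_mask(image, vessel, disc, params),
                 error = function(e) {
                   if (grepl("rps_gradability_error", conditionMessage(e))) NULL
                   else stop(e)
                 })
  if (is.null(bg)) {
    bg_empty <- binary_mask(matrix(0L, image$height, image$width),
                            "retinal_background", "derived")
    q <- assess_gradability(image, bg_empty, params = params)
    row$reasons <- paste(q$reasons, collapse = "; ")
    return(row)
  }
  q <- assess_gradability(image, bg, params = params)
  if (!q$pass) {
    row$reasons <- paste(q$reasons, collapse = "; ")
    return(row)
  }
  ch <- background_chromaticity(image, bg, method = chroma_method)
  row$gradable <- TRUE
  row$median_R <- ch$rgb[["R"]]; row$median_G <- ch$rgb[["G"]]
  row$median_B <- ch$rgb[["B"]]
  row$L <- ch$lab[["L"]]; row$a <- ch$lab[["a"]]; row$b <- ch$lab[["b"]]
  if (!is.null(model)) row$rps <- rps_project(model, ch$chroma)
  row
}

# resolve (image, vessel, disc) for row i of a cohort table or manifest df
load_record <- function(tab, i, mask_source = c("provided", "baseline"),
                        params = masking_params()) {
  mask_source <- match.arg(mask_source)
  if (inherits(tab, "synth_cohort")) {
    g <- render_cohort_row(tab, i)
    rec <- list(image = g$image, vessel = g$vessel, disc = g$disc)
  } else {
    img <- read_fundus_image(tab$image_path[i],
                             image_id = if ("image_id" %in% names(tab))
                               tab$image_id[i] else basename(tab$image_path[i]),
                             participant_id = tab$participant_id[i],
                             eye = tab$eye[i],
                             repeat_index = tab$repeat_index[i])
    shape <- c(img$height, img$width)
    rec <- list(image = img, vessel = NULL, disc = NULL)
    if (!is.na(tab$vessel_mask_path[i])) {
      rec$vessel <- read_mask(tab$vessel_mask_path[i], shape, "vessel")
    }
    if (!is.na(tab$disc_mask_path[i])) {
      rec$disc <- read_mask(tab$disc_mask_path[i], shape, "disc")
    }
  }
  if (mask_source == "baseline" || is.null(rec$vessel) || is.null(rec$disc)) {
    seg <- segment_baseline(rec$image, params)
    if (mask_source == "baseline" || is.null(rec$vessel)) rec$vessel <- seg$vessel
    if (mask_source == "baseline" || is.null(rec$disc)) rec$disc <- seg$disc
  }
  rec
}

#' Score a whole cohort
#'
#' Accepts either an in-memory [simulate_cohort()] specification (images are
#' rendered on the fly) or a manifest data frame from [read_manifest()]
#' (images and masks are read from disk). When a manifest row lacks mask
#' paths — or `mask_source = "baseline"` is forced — the classical
#' [segment_baseline()] segmenter fills in.
#'
#' @param cohort `synth_cohort` or manifest data frame.
#' @param params A [masking_params()].
#' @param model Optional [rps_fit()] model to apply while scoring.
#' @param mask_source `"provided"` (default; truth or ingested masks) or
#'   `"baseline"`.
#' @param chroma_method Passed to [background_chromaticity()].
#' @return Data frame of per-image score rows (see [write_scores()]).
#' @export
score_cohort <- function(cohort, params = masking_params(), model = NULL,
                         mask_source = c("provided", "baseline"),
                         chroma_method = c("median_rgb", "median_lab")) {
  mask_source <- match.arg(mask_source)
  chroma_method <- match.arg(chroma_method)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- load_record(cohort, i, mask_source, params)
    rows[[i]] <- score_image(rec$image, rec$vessel, rec$disc, params,
                             model = model, chroma_method = chroma_method)
  }
  do.call(rbind, rows)
}

#' Fit an RPS model from a score table
#'
#' Fits the PCA scale to the chromaticities of all gradable images (the
#' fit population is every image, not per-participant means).
#'
#' @param scores Data frame from [score_cohort()] / [read_scores()].
#' @param variables Columns to fit; default `c("a", "b")`.
#' @return An `rps_model`.
#' @export
fit_rps_from_scores <- function(scores, variables = c("a", "b")) {
  ok <- scores$gradable & is.finite(scores$a) & is.finite(scores$b)
  if (sum(ok) < 3) {
    stop("rps_fitting_error: fewer than 3 gradable images", call. = FALSE)
  }
  rps_fit(scores[ok, , drop = FALSE], variables = variables)
}

#' Add RPS (and z-scored RPS) to a score table using a fitted model
#'
#' @param scores Score table with `a`, `b` columns.
#' @param model An `rps_model`.
#' @return The table with `rps` filled for gradable rows and an `rps_z`
#'   column standardised over gradable rows.
#' @export
apply_rps_model <- function(scores, model) {
  ok <- scores$gradable & is.finite(scores$a) & is.finite(scores$b)
  scores$rps <- NA_real_
  pts <- scores[ok, model$variables, drop = FALSE]
  scores$rps[ok] <- rps_project(model, pts)
  scores$rps_z <- NA_real_
  if (sum(ok) >= 2) scores$rps_z[ok] <- rps_zscore(scores$rps[ok])
  scores
}

#' Mask-perturbation sensitivity analysis
#'
#' For each image, the combined vessel-and-disc mask is randomly perturbed
#' (one iteration of 3x3 binary erosion or dilation, chosen with
#' probability 1/2 by a per-image-per-replicate seed), the background is
#' re-derived and the image re-scored. The change in RPS is reported in
#' cohort-SD units, quantifying how robust the score is to segmentation
#' area errors.
#'
#' @param cohort `synth_cohort` or manifest data frame.
#' @param model A fitted `rps_model` used for all scorings.
#' @param n_seeds Perturbation replicates per image. Default 10.
#' @param seed Base seed from which per-replicate seeds derive.
#' @param params A [masking_params()].
#' @param mask_source Passed to [load_record()].
#' @return List with `detail` (one row per image x replicate: `rps0`,
#'   `rps_perturbed`, `delta`, `delta_sd_units`, `operation`) and `summary`
#'   (cohort SD, median and 90th percentile of `|delta|` in SD units).
#' @export
sensitivity_analysis <- function(cohort, model, n_seeds = 10L, seed = 1L,
                                 params = masking_params(),
                                 mask_source = c("provided", "baseline")) {
  mask_source <- match.arg(mask_source)
  n <- nrow(cohort)
  out <- list(); k <- 0L
  rps0_all <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rec <- load_record(cohort, i, mask_source, params)
    base_row <- score_image(rec$image, rec$vessel, rec$disc, params,
                            model = model)
    rps0_all[i] <- base_row$rps
    if (!isTRUE(base_row$gradable)) next
    gray <- to_grayscale(rec$image, params)
    border <- detect_border(gray, params)
    vd <- binary_mask(((mask_values(rec$vessel) +
                          mask_values(rec$disc)) > 0) * 1L, "combined")
    for (j in seq_len(n_seeds)) {
      pseed <- (as.numeric(seed) * 1000003 + i * 1009 + j) %% 2147483647
      pvd <- perturb_mask(vd, as.integer(pseed))
      row <- tryCatch({
        excl <- build_exclusion_mask(pvd, matrix(0L, nrow(gray), ncol(gray)),
                                     border, params, width = rec$image$width)
        bg <- binary_mask(1L - excl$values, "retinal_background")
        if (sum(bg$values) == 0) stop("rps_gradability_error: empty")
        ch <- background_chromaticity(rec$image, bg)
        data.frame(image_id = rec$image$image_id, replicate = j,
                   operation = attr(pvd, "operation"),
                   rps0 = base_row$rps,
                   rps_perturbed = rps_project(model, ch$chroma),
                   stringsAsFactors = FALSE)
      }, error = function(e) NULL)
      if (!is.null(row)) { k <- k + 1L; out[[k]] <- row }
    }
  }
  detail <- do.call(rbind, out)
  cohort_sd <- stats::sd(rps0_all[is.finite(rps0_all)])
  detail$delta <- detail$rps_perturbed - detail$rps0
  detail$delta_sd_units <- detail$delta / cohort_sd
  list(detail = detail,
       summary = list(
         cohort_sd = cohort_sd,
         n_images = sum(is.finite(rps0_all)),
         n_rows = nrow(detail),
         median_abs_delta_sd = stats::median(abs(detail$delta_sd_units)),
         q90_abs_delta_sd = stats::quantile(abs(detail$delta_sd_units), 0.9,
                                            names = FALSE)))
}
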