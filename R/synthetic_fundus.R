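#' Parameters for the synthetic fundus generator
#'
#' The generator renders a fundus-like circular field of view on a black
#' surround: a background whose colour is driven by a scalar pigment
#' parameter, a random-walk vessel tree (darker than background), a bright
#' optic disc, an optional illumination plane in L*, and sensor noise.
#' Ground-truth vessel and disc masks are pixel-exact by construction.
#'
#' The pigment parameter in \[0, 1\] maps linearly to a background CIELAB
#' triple: L* 75 to 35, a* 10 to 30, b* 25 to 45 as pigment goes 0 to 1 —
#' a ramp from a light yellow-orange fundus to a dark red-brown one. The
#' anchors are plausible fundus tones chosen for unambiguous ground-truth
#' ordering; the absolute values are synthetic conventions.
#'
#' @param width,height Image size in pixels (>= 64). Default 128.
#' @param pigment Scalar in \[0, 1\] driving background colour.
#' @param vessel_density Target vessel foreground fraction of the field of
#'   view. Default 0.06.
#' @param disc_radius_frac Optic-disc radius as a fraction of the field
#'   radius. Default 0.12.
#' @param illumination_sd SD (L* units) of the random per-image illumination
#'   plane: a DC brightness offset drawn with this SD plus a linear tilt
#'   with half this within-image SD. Default 0.
#' @param illumination_offset Deterministic additive L* offset applied to
#'   the whole field (useful for controlled luminance-shift experiments).
#'   Default 0.
#' @param noise_sd Acquisition noise SD in 8-bit units, applied per channel
#'   as i.i.d. pixel noise plus a per-acquisition channel gain offset of
#'   the same SD (white-balance / exposure variation between captures).
#'   Default 2.
#' @param quantize Quantise pixels to 8-bit integers (default TRUE). Set
#'   FALSE for continuous-valued rasters in quantisation-free experiments.
#' @param vessels,disc Render the vessel tree / the optic disc. Default TRUE.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(width = 128L, height = 128L, pigment = 0.5,
                         vessel_density = 0.06, disc_radius_frac = 0.12,
                         illumination_sd = 0, illumination_offset = 0,
                         noise_sd = 2, quantize = TRUE,
                         vessels = TRUE, disc = TRUE, seed = 1L) {
  stopifnot(width >= 64, height >= 64, pigment >= 0, pigment <= 1,
            vessel_density >= 0, vessel_density < 1,
            disc_radius_frac >= 0, illumination_sd >= 0, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pigment = pigment, vessel_density = vessel_density,
                 disc_radius_frac = disc_radius_frac,
                 illumination_sd = illumination_sd,
                 illumination_offset = illumination_offset,
                 noise_sd = noise_sd, quantize = quantize,
                 vessels = vessels, disc = disc, seed = as.integer(seed)),
            class = "synth_params")
}

#' Background CIELAB colour for a pigment level
#'
#' Linear ramp in Lab space: more pigment means darker (lower L*), redder
#' (higher a*) and yellower-brown (higher b*) background tissue.
#'
#' @param pigment Scalar or vector in \[0, 1\].
#' @return Matrix (or named vector for a scalar) with columns `L`, `a`, `b`.
#' @export
pigment_ramp <- function(pigment) {
  stopifnot(all(pigment >= 0), all(pigment <= 1))
  out <- cbind(L = 75 - 40 * pigment,
               a = 10 + 20 * pigment,
               b = 25 + 20 * pigment)
  if (length(pigment) == 1) out[1, ] else out
}

# stamp a thick polyline onto a logical mask; pts is n x 2 (row, col)
stamp_points <- function(mask, pts, thickness, field) {
  h <- nrow(mask); w <- ncol(mask)
  r <- max(0L, as.integer(thickness) %/% 2L)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 0.5, ]
  rows <- outer(pts[, 1], off$dr, "+")
  cols <- outer(pts[, 2], off$dc, "+")
  keep <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  idx <- cbind(rows[keep], cols[keep])
  idx <- idx[field[idx], , drop = FALSE]
  mask[idx] <- TRUE
  mask
}

#' Generate one synthetic fundus image with ground truth
#'
#' Fully deterministic given `params$seed`. The black surround guarantees
#' that percentile-based border detection recovers it exactly; the returned
#' truth masks are the pixels actually rendered as vessel / disc.
#'
#' @param params A [synth_params()].
#' @param image_id,participant_id,eye,repeat_index Metadata passed through
#'   to the [fundus_image()].
#' @return List with `image` ([fundus_image()]), `vessel` and `disc` truth
#'   masks ([binary_mask()]), `lab_true` (the background Lab triple before
#'   illumination) and `pigment`.
#' @export
generate_fundus <- function(params = synth_params(), image_id = "synth",
                            participant_id = "p1", eye = "right",
                            repeat_index = 1L) {
  stopifnot(inherits(params, "synth_params"))
  w <- params$width; h <- params$height
  field_r <- 0.47 * min(w, h)
  disc_r <- params$disc_radius_frac * field_r
  disc_dist <- 0.55 * field_r
  if (params$disc && disc_dist + disc_r > field_r) {
    stop("rps_parameter_error: optic disc would exceed the field of view",
         call. = FALSE)
  }
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  field <- (yy - cy)^2 + (xx - cx)^2 <= field_r^2

  bg <- pigment_ramp(params$pigment)

  with_local_seed(params$seed, {
    # optic disc: on the nasal side, mirrored by laterality, angle jittered
    disc_mask <- matrix(FALSE, h, w)
    disc_cy <- cy; disc_cx <- cx
    if (params$disc) {
      theta <- (if (identical(eye, "right")) 0 else pi) +
        stats::runif(1, -0.3, 0.3)
      disc_cy <- cy + disc_dist * sin(theta)
      disc_cx <- cx + disc_dist * cos(theta)
      disc_mask <- (yy - disc_cy)^2 + (xx - disc_cx)^2 <= disc_r^2
      disc_mask <- disc_mask & field
    }

    # vessel tree: random walks radiating from the disc centre
    vessel_mask <- matrix(FALSE, h, w)
    if (params$vessels && params$vessel_density > 0) {
      thickness <- max(2L, as.integer(round(w / 60)))
      n_field <- sum(field)
      n_steps <- as.integer(round(2.4 * field_r))
      branch <- 0L
      while (mean(vessel_mask[field]) < params$vessel_density &&
             branch < 64L) {
        branch <- branch + 1L
        ang <- stats::runif(1, 0, 2 * pi)
        pos <- c(disc_cy, disc_cx)
        pts <- matrix(NA_real_, n_steps, 2)
        for (s in seq_len(n_steps)) {
          pos <- pos + c(sin(ang), cos(ang))
          ang <- ang + stats::rnorm(1, 0, 0.18)
          if ((pos[1] - cy)^2 + (pos[2] - cx)^2 > field_r^2) break
          pts[s, ] <- pos
        }
        pts <- pts[stats::complete.cases(pts), , drop = FALSE]
        if (nrow(pts) > 0) {
          vessel_mask <- stamp_points(vessel_mask, round(pts), thickness,
                                      field)
        }
      }
      vessel_mask <- vessel_mask & !disc_mask
    }

    # compose Lab planes
    Lp <- matrix(bg[["L"]], h, w)
    ap <- matrix(bg[["a"]], h, w)
    bp <- matrix(bg[["b"]], h, w)
    if (params$disc) {
      Lp[disc_mask] <- min(bg[["L"]] + 28, 95)
      ap[disc_mask] <- 6
      bp[disc_mask] <- 38
    }
    if (any(vessel_mask)) {
      Lp[vessel_mask] <- Lp[vessel_mask] - 22
      ap[vessel_mask] <- ap[vessel_mask] + 10
      bp[vessel_mask] <- bp[vessel_mask] - 10
    }

    # illumination: DC offset plus a linear tilt, in L* units
    if (params$illumination_sd > 0) {
      dc <- stats::rnorm(1, 0, params$illumination_sd)
      phi <- stats::runif(1, 0, 2 * pi)
      tilt <- cos(phi) * (xx - cx) + sin(phi) * (yy - cy)
      tilt_sd <- stats::sd(tilt[field])
      tilt <- if (tilt_sd > 0)
        tilt / tilt_sd * (params$illumination_sd / 2) else tilt * 0
      Lp <- Lp + dc + tilt
    }
    Lp <- Lp + params$illumination_offset
    Lp <- pmin(pmax(Lp, 0), 100)

    # render field pixels to sRGB
    px <- array(0, dim = c(h, w, 3))
    idx <- which(field)
    rgb <- lab_to_srgb(cbind(Lp[idx], ap[idx], bp[idx]))
    if (params$noise_sd > 0) {
      # acquisition noise has two parts, both with SD noise_sd in 8-bit
      # units: i.i.d. per-pixel sensor noise, and a per-acquisition
      # per-channel gain offset (white-balance / exposure variation between
      # captures). The offset is what limits repeatability of a spatial
      # median; pixel noise alone would be averaged away.
      gain <- stats::rnorm(3, 0, params$noise_sd)
      rgb <- sweep(rgb, 2, gain, "+") +
        matrix(stats::rnorm(length(rgb), 0, params$noise_sd), nrow(rgb), 3)
    }
    rgb <- pmin(pmax(rgb, 0), 255)
    # keep rendered tissue strictly above the black surround so the border
    # percentile rule separates the two even for very dark pigment
    rgb <- pmax(rgb, 1)
    if (params$quantize) rgb <- round(rgb)
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[idx] <- rgb[, ch]
      px[, , ch] <- plane
    }

    list(image = fundus_image(px, image_id = image_id,
                              participant_id = participant_id, eye = eye,
                              repeat_index = repeat_index),
         vessel = binary_mask(vessel_mask * 1L, "vessel", "derived"),
         disc = binary_mask(disc_mask * 1L, "disc", "derived"),
         lab_true = bg, pigment = params$pigment)
  })
}

#' Simulate a cohort design
#'
#' Draws per-participant pigment levels and lays out a cohort of images —
#' optionally two eyes per participant with correlated pigment, and repeat
#' acquisitions per eye differing only in noise/illumination — as a
#' specification table. Each row carries its own seed, so images can be
#' rendered lazily (by [score_cohort()]) or materialised to disk with
#' [write_cohort()]; both routes are fully reproducible.
#'
#' @param n_participants Number of participants (>= 3 for downstream fits).
#' @param eyes Character vector of eyes per participant, e.g.
#'   `c("right", "left")`.
#' @param repeats Repeat acquisitions per eye. Default 1.
#' @param pigment_sampler Function `n -> n pigment values in [0,1]`.
#'   Default `stats::runif`.
#' @param eye_pigment_sd SD of the per-eye deviation from the participant's
#'   pigment (inter-eye biological variation), clamped to \[0, 1\].
#'   Default 0.02.
#' @param base_params A [synth_params()] supplying the shared rendering
#'   parameters (size, noise, illumination, ...).
#' @param seed Cohort-level seed; per-image seeds are drawn from it.
#' @return Data frame of class `synth_cohort`: one row per image with
#'   `image_id`, `participant_id`, `eye`, `repeat_index`, `pigment`,
#'   `seed`, and the true background `L`, `a`, `b`.
#' @export
simulate_cohort <- function(n_participants, eyes = c("right", "left"),
                            repeats = 1L,
                            pigment_sampler = stats::runif,
                            eye_pigment_sd = 0.02,
                            base_params = synth_params(), seed = 1L) {
  stopifnot(n_participants >= 3, length(eyes) >= 1, repeats >= 1)
  with_local_seed(seed, {
    pig_part <- pigment_sampler(n_participants)
    stopifnot(all(pig_part >= 0), all(pig_part <= 1))
    rows <- list()
    k <- 0L
    for (i in seq_len(n_participants)) {
      pid <- sprintf("p%04d", i)
      for (e in eyes) {
        pig_eye <- min(max(pig_part[i] + stats::rnorm(1, 0, eye_pigment_sd),
                           0), 1)
        for (r in seq_len(repeats)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            image_id = sprintf("%s_%s_r%d", pid, e, r),
            participant_id = pid, eye = e, repeat_index = r,
            pigment = pig_eye,
            seed = sample.int(.Machine$integer.max - 1L, 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    lab <- pigment_ramp(out$pigment)
    out$L <- lab[, "L"]; out$a <- lab[, "a"]; out$b <- lab[, "b"]
    attr(out, "base_params") <- base_params
    class(out) <- c("synth_cohort", "data.frame")
    out
  })
}

cohort_row_params <- function(cohort, i) {
  p <- attr(cohort, "base_params")
  p$pigment <- cohort$pigment[i]
  p$seed <- cohort$seed[i]
  p
}

# render the i-th image of a cohort table
render_cohort_row <- function(cohort, i) {
  generate_fundus(cohort_row_params(cohort, i),
                  image_id = cohort$image_id[i],
                  participant_id = cohort$participant_id[i],
                  eye = cohort$eye[i],
                  repeat_index = cohort$repeat_index[i])
}

#' Materialise a simulated cohort to disk
#'
#' Renders every image of a [simulate_cohort()] specification, writing PNG
#' images, ground-truth vessel and disc masks, a `manifest.csv` understood
#' by [read_manifest()], and a `truth.csv` with the pigment and true Lab
#' background per image.
#'
#' @param cohort A `synth_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort)
  man <- data.frame(image_path = character(n), participant_id = cohort$participant_id,
                    eye = cohort$eye, repeat_index = cohort$repeat_index,
                    vessel_mask_path = character(n),
                    disc_mask_path = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- render_cohort_row(cohort, i)
    id <- cohort$image_id[i]
    man$image_path[i] <- paste0(id, ".png")
    man$vessel_mask_path[i] <- paste0(id, "_vessel.png")
    man$disc_mask_path[i] <- paste0(id, "_disc.png")
    write_fundus_image(g$image, file.path(dir, man$image_path[i]))
    write_mask(g$vessel, file.path(dir, man$vessel_mask_path[i]))
    write_mask(g$disc, file.path(dir, man$disc_mask_path[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- cohort[, c("image_id", "participant_id", "eye", "repeat_index",
                      "pigment", "L", "a", "b")]
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(man)
}
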