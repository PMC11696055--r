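test_that("image write/read round-trips pixels and takes metadata from the caller", {
  g <- generate_fundus(synth_params(seed = 3), image_id = "a",
                       participant_id = "p9", eye = "left", repeat_index = 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_fundus_image(g$image, path)
  back <- read_fundus_image(path, image_id = "a", participant_id = "p9",
                            eye = "left", repeat_index = 2)
  expect_identical(back$pixels, g$image$pixels)
  expect_equal(back$width, 128)
  expect_equal(back$participant_id, "p9")
  expect_equal(back$eye, "left")
})

test_that("degenerate rasters and unreadable files are rejected", {
  expect_error(fundus_image(array(0, c(10, 10, 3))), "64x64")
  expect_error(fundus_image(array(300, c(64, 64, 3))), "\\[0, 255\\]")
  expect_error(read_fundus_image("/nonexistent/file.png"), "rps_io_error")
  # grayscale input names the channel count
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(matrix(0.5, 64, 64)), path)
  expect_error(read_fundus_image(path), "1 channel")
  # truncated file yields an I/O error, not a partial object
  trunc <- withr::local_tempfile(fileext = ".png")
  writeBin(readBin(path, "raw", 30), trunc)
  expect_error(read_fundus_image(trunc), "rps_io_error")
})

test_that("masks threshold at nonzero and enforce shape alignment", {
  path <- withr::local_tempfile(fileext = ".png")
  v <- matrix(0, 64, 64); v[10:20, 10:20] <- 1
  write_mask(binary_mask(v, "disc"), path)
  m <- read_mask(path, c(64, 64), "disc")
  expect_identical(m$values, matrix(as.integer(v), 64, 64))
  expect_error(read_mask(path, c(65, 64)), "rps_alignment_error.*64x64")
  # antialiased grey pixels count as foreground
  EBImage::writeImage(EBImage::Image(matrix(c(0, 0.3), 64, 64)), path)
  m2 <- read_mask(path, c(64, 64))
  expect_equal(sum(m2$values), 64 * 32)
})

test_that("manifest loading preserves order and validates keys and paths", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(3, eyes = "right",
                        base_params = synth_params(width = 64, height = 64),
                        seed = 11)
  write_cohort(co, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man$participant_id, co$participant_id)
  expect_true(all(file.exists(man$image_path)))

  bad <- utils::read.csv(file.path(dir, "manifest.csv"))
  bad$repeat_index <- 1
  bad$participant_id <- "same"
  f <- file.path(dir, "dup.csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_manifest(f), "duplicate")

  bad2 <- utils::read.csv(file.path(dir, "manifest.csv"))
  bad2$image_path[1] <- "missing.png"
  f2 <- file.path(dir, "missing.csv")
  utils::write.csv(bad2, f2, row.names = FALSE)
  expect_error(read_manifest(f2), "missing file")
})

test_that("score tables round-trip, including ungradable rows and empty tables", {
  co <- simulate_cohort(3, eyes = "right",
                        base_params = synth_params(width = 64, height = 64),
                        seed = 2)
  sc <- score_cohort(co)
  sc$rps[1] <- NA_real_  # an unscored image leaves an empty cell
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(sc, path)
  back <- read_scores(path)
  expect_equal(back$a, sc$a, tolerance = 1e-12)
  expect_equal(back$gradable, sc$gradable)
  expect_true(is.na(back$rps[1]))

  write_scores(sc[0, ], path)
  expect_equal(nrow(read_scores(path)), 0)
})

test_that("model persistence reproduces projections exactly and refuses bad files", {
  set.seed(4)
  pts <- cbind(a = rnorm(40, 20, 4), b = rnorm(40, 35, 2) + 0.5 * rnorm(40))
  m <- rps_fit(pts)
  path <- withr::local_tempfile(fileext = ".json")
  save_rps_model(m, path)
  m2 <- load_rps_model(path)
  probe <- cbind(a = c(0, 15, 33.3), b = c(0, 40, 21.7))
  expect_identical(rps_project(m2, probe), rps_project(m, probe))

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$eigenvectors <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  expect_error(load_rps_model(path), "rps_schema_error.*eigenvectors")

  obj2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj2$format_version <- "99"
  jsonlite::write_json(obj2, path, digits = NA, auto_unbox = TRUE)
  expect_error(load_rps_model(path), "rps_version_error")
})

test_that("a persisted model projects points from another cohort as stored algebra dictates", {
  set.seed(5)
  pts <- cbind(a = rnorm(30, 18, 3), b = rnorm(30, 33, 1.5))
  m <- rps_fit(pts)
  path <- withr::local_tempfile(fileext = ".json")
  save_rps_model(m, path)
  m2 <- load_rps_model(path)
  p_new <- c(a = 40, b = 10)  # a cohort-B-like point far from the fit cloud
  by_hand <- m2$orientation *
    sum((p_new - m2$mean) * m2$eigenvectors[1, ])
  expect_equal(rps_project(m2, p_new), by_hand, tolerance = 1e-12)
  expect_true(is.finite(by_hand))
})
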