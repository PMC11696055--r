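test_that("grayscale conversion uses Rec.601 luma", {
  px <- array(0, c(64, 64, 3))
  img <- fundus_image(px + 255)
  expect_true(all(to_grayscale(img) == 255))
  px[, , 1] <- 255
  expect_equal(to_grayscale(fundus_image(px))[1, 1], 76.245)
  const <- to_grayscale(fundus_image(array(123, c(64, 64, 3))))
  expect_equal(range(const), c(123, 123))
})

test_that("border detection flags all and only pixels at or below the percentile", {
  # black surround fixture: exactly the zero pixels are flagged
  img <- flat_fundus(surround = 8)
  b <- detect_border(to_grayscale(img))
  expect_identical(b$values, (to_grayscale(img) == 0) * 1L)

  # strictly increasing ramp vs brute-force sort oracle
  gray <- matrix(seq_len(200 * 200), 200, 200)
  b2 <- detect_border(gray)$values
  expect_identical(b2, brute_border(gray, 0.5))
  expect_equal(sum(b2), 200)  # 0.5% of 40000, exact for a strict ramp

  # constant image: percentile equals the constant, all flagged
  expect_true(all(detect_border(matrix(255, 64, 64))$values == 1L))
})

test_that("random images match the brute-force border oracle", {
  set.seed(101)
  for (i in 1:25) {
    gray <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
    expect_identical(detect_border(gray)$values, brute_border(gray, 0.5))
  }
})

test_that("dilation iteration count follows round(4 * width / 600)", {
  expect_identical(dilation_iterations(600), 4L)
  expect_identical(dilation_iterations(1200), 8L)
  expect_identical(dilation_iterations(2048), 14L)   # 13.653...
  # half-to-even at the .5 boundary
  expect_identical(dilation_iterations(75), 0L)      # 0.5 -> 0
  expect_identical(dilation_iterations(225), 2L)     # 1.5 -> 2
  # non-decreasing in width
  iters <- vapply(seq(64, 3000, by = 16), dilation_iterations, 1L)
  expect_true(all(diff(iters) >= 0))
})

test_that("exclusion mask equals union then repeated 8-neighbour dilation", {
  empty <- matrix(0L, 40, 40)
  out <- build_exclusion_mask(empty, empty, empty, width = 600)
  expect_equal(sum(out$values), 0)

  # single centre pixel at reference width: 4 iterations -> 9x9 square
  v <- empty; v[20, 20] <- 1L
  out2 <- build_exclusion_mask(v, empty, empty, width = 600)
  expect_equal(attr(out2, "iterations"), 4L)
  expect_identical(out2$values, brute_dilate(v, 4))
  expect_equal(sum(out2$values), 81)

  # monotonicity: adding foreground never removes output pixels
  v2 <- v; v2[5, 30] <- 1L
  out3 <- build_exclusion_mask(v2, empty, empty, width = 600)
  expect_true(all(out3$values >= out2$values))

  expect_error(build_exclusion_mask(v, matrix(0L, 39, 40), empty),
               "rps_alignment_error")
})

test_that("n-iteration dilation equals n composed single dilations on random masks", {
  set.seed(77)
  for (trial in 1:20) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    m <- matrix(rbinom(h * w, 1, 0.08), h, w)
    n <- sample(0:3, 1)
    expect_identical(binary_dilate(m, n), brute_dilate(m, n))
  }
})

test_that("background mask complements the exclusion mask and shrinks with iterations", {
  g <- generate_fundus(synth_params(seed = 9, noise_sd = 0))
  fracs <- vapply(0:8, function(it) {
    p <- masking_params(dilation_scale = it, reference_width = 128)
    bg <- retinal_background_mask(g$image, g$vessel, g$disc, p)
    attr(bg, "n_pixels") / length(bg$values)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))

  # empty inputs: background = full image minus the detected border
  empty <- matrix(0L, 128, 128)
  p0 <- masking_params(dilation_scale = 0)
  bg0 <- retinal_background_mask(g$image, empty, empty, p0)
  border <- detect_border(to_grayscale(g$image), p0)
  expect_identical(bg0$values, 1L - border$values)

  # exclusion covering everything is a gradability error
  full <- matrix(1L, 128, 128)
  expect_error(retinal_background_mask(g$image, full, empty),
               "rps_gradability_error")
})

test_that("mask perturbation is a seeded coin flip between 3x3 erosion and dilation", {
  m <- matrix(0L, 16, 16); m[6:10, 6:10] <- 1L
  p1 <- perturb_mask(m, 42)
  p2 <- perturb_mask(m, 42)
  expect_identical(p1$values, p2$values)
  expect_identical(attr(p1, "operation"), attr(p2, "operation"))

  # erosion wipes out an isolated pixel; dilation grows the square by 1
  single <- matrix(0L, 16, 16); single[8, 8] <- 1L
  ops <- vapply(1:1000, function(s) attr(perturb_mask(single, s), "operation"),
                character(1))
  er <- perturb_mask(single, which(ops == "erosion")[1])
  expect_equal(sum(er$values), 0)
  di <- perturb_mask(single, which(ops == "dilation")[1])
  expect_equal(sum(di$values), 9)

  # seeded coin is fair: 3 sigma binomial bound over 1000 seeds
  n_er <- sum(ops == "erosion")
  expect_lt(abs(n_er - 500), 3 * sqrt(1000 * 0.25))
})

test_that("perturbation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(perturb_mask(matrix(1L, 16, 16), 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("baseline segmenter finds vessels and disc on synthetic fixtures", {
  for (seed in c(21, 22, 23)) {
    g <- generate_fundus(synth_params(seed = seed, pigment = 0.3 + 0.2 * (seed - 21),
                                      noise_sd = 2))
    seg <- segment_baseline(g$image)
    expect_gte(dice_coef(seg$vessel$values == 1L, g$vessel$values == 1L), 0.7)
    d_true <- mask_centroid(g$disc$values)
    d_est <- mask_centroid(seg$disc$values)
    r_true <- sqrt(sum(g$disc$values) / pi)
    expect_lt(sqrt(sum((d_true - d_est)^2)), 2 * r_true)
  }
  g0 <- generate_fundus(synth_params(seed = 31, vessels = FALSE, noise_sd = 2))
  seg0 <- segment_baseline(g0$image)
  field_area <- sum(detect_border(to_grayscale(g0$image))$values == 0L)
  expect_lt(sum(seg0$vessel$values) / field_area, 0.02)
})

test_that("gradability gate passes clean images and names failure reasons", {
  g <- generate_fundus(synth_params(seed = 12, noise_sd = 2))
  bg <- retinal_background_mask(g$image, g$vessel, g$disc)
  expect_true(assess_gradability(g$image, bg)$pass)

  black <- fundus_image(array(0, c(64, 64, 3)))
  empty_bg <- binary_mask(matrix(0L, 64, 64), "retinal_background")
  qb <- assess_gradability(black, empty_bg)
  expect_false(qb$pass)
  expect_true("empty background" %in% qb$reasons)

  white <- fundus_image(array(255, c(64, 64, 3)))
  qw <- assess_gradability(white, empty_bg)
  expect_false(qw$pass)
  expect_true("saturation" %in% qw$reasons)
})
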