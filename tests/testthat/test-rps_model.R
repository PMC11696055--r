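test_that("collinear clouds give proportional eigenvalues (1, 0)", {
  a <- c(-2, -1, 0, 1, 2)
  m <- rps_fit(cbind(a = a, b = 2 * a))
  expect_equal(m$proportional_eigenvalues, c(1, 0), tolerance = 1e-12)
  expect_equal(sum(m$proportional_eigenvalues), 1, tolerance = 1e-12)
})

test_that("a dominant a-axis cloud is oriented so scores increase with a*", {
  # {(+-1, 0), (0, +-0.1)}: covariance diag(2/3, 0.02/3), first axis = a
  pts <- cbind(a = c(1, -1, 0, 0), b = c(0, 0, 0.1, -0.1))
  m <- rps_fit(pts)
  expect_equal(abs(m$eigenvectors[1, ]), c(1, 0), tolerance = 1e-12)
  expect_equal(m$eigenvalues, c(2 / 3, 0.02 / 3), tolerance = 1e-12)
  expect_equal(rps_project(m, c(a = 1, b = 0)), 1, tolerance = 1e-12)
  expect_equal(rps_project(m, m$mean), 0, tolerance = 1e-12)
})

test_that("isotropic clouds split variance evenly", {
  set.seed(60)
  pts <- cbind(a = rnorm(1e5), b = rnorm(1e5))
  m <- rps_fit(pts)
  expect_equal(m$proportional_eigenvalues[1], 0.5, tolerance = 0.01)
})

test_that("projection variance equals the first eigenvalue on the fitting cohort", {
  set.seed(61)
  pts <- cbind(a = rnorm(500, 20, 5), b = rnorm(500, 35, 2))
  m <- rps_fit(pts)
  proj <- rps_project(m, pts)
  expect_equal(stats::var(proj), m$eigenvalues[1], tolerance = 1e-8)
  # and the fit agrees with stats::prcomp up to component sign
  pc <- stats::prcomp(pts)
  expect_equal(m$eigenvalues, unname(pc$sdev^2), tolerance = 1e-10)
  expect_equal(abs(proj), abs(pc$x[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are refused", {
  expect_error(rps_fit(cbind(a = c(1, 2), b = c(1, 2))), "at least 3")
  expect_error(rps_fit(cbind(a = c(1, 1, 1), b = c(2, 2, 2))),
               "zero-variance")
  m <- rps_fit(cbind(a = rnorm(10), b = rnorm(10)))
  expect_error(rps_project(m, c(a = NA, b = 1)), "rps_projection_error")
})

test_that("fit-project is rotation-equivariant up to the corrected sign", {
  set.seed(62)
  pts <- cbind(a = rnorm(200, 0, 3), b = rnorm(200, 0, 1))
  s1 <- rps_project(rps_fit(pts), pts)
  for (theta in c(0.3, 1.1, 2.6)) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    rot <- pts %*% t(R); colnames(rot) <- c("a", "b")
    s2 <- rps_project(rps_fit(rot), rot)
    expect_lt(min(max(abs(s1 - s2)), max(abs(s1 + s2))), 1e-8)
  }
})

test_that("participant means average available gradable eyes", {
  df <- data.frame(participant_id = c("x", "x", "y"),
                   rps = c(2, 4, 5))
  out <- mean_rps_per_participant(df)
  expect_equal(out$rps_mean, c(3, 5))
  expect_equal(out$n_eyes, c(2L, 1L))

  # 10-row fixture vs hand aggregation; non-finite rows are dropped
  set.seed(63)
  df2 <- data.frame(participant_id = rep(sprintf("p%d", 1:5), each = 2),
                    rps = rnorm(10))
  df2$rps[3] <- NA
  out2 <- mean_rps_per_participant(df2)
  for (p in unique(df2$participant_id)) {
    v <- df2$rps[df2$participant_id == p]
    expect_equal(out2$rps_mean[out2$participant_id == p],
                 mean(v[is.finite(v)]))
  }
  expect_equal(nrow(mean_rps_per_participant(
    data.frame(participant_id = "z", rps = NA_real_))), 0)
})

test_that("z-scoring standardises to mean 0, SD 1 and rejects zero spread", {
  expect_equal(rps_zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(64)
  z <- rps_zscore(rnorm(100, 50, 9))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_error(rps_zscore(c(5, 5, 5)), "rps_standardisation_error")
  expect_error(rps_zscore(3), "rps_standardisation_error")
})

test_that("model transfer is linear: parallel shifts move scores, orthogonal ones do not", {
  set.seed(65)
  A <- cbind(a = rnorm(300, 20, 4), b = rnorm(300, 35, 1.5))
  m <- rps_fit(A)
  sA <- rps_project(m, A)
  expect_identical(rps_project(m, A), sA)  # identical cohort, identical scores

  v1 <- m$eigenvectors[1, ] * m$orientation
  delta <- 3.7
  B_par <- sweep(A, 2, -delta * v1); colnames(B_par) <- c("a", "b")
  expect_equal(rps_project(m, B_par), sA + delta, tolerance = 1e-9)

  v2 <- m$eigenvectors[2, ]
  expect_lt(abs(sum(v2 * m$eigenvectors[1, ])), 1e-12)
  B_orth <- sweep(A, 2, -2.5 * v2); colnames(B_orth) <- c("a", "b")
  expect_equal(rps_project(m, B_orth), sA, tolerance = 1e-9)
})
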