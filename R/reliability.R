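#' One-way intraclass correlation, ICC(1,1)
#'
#' Single-rater intraclass correlation from the one-way random-effects
#' ANOVA (Shrout–Fleiss ICC(1,1)):
#' \deqn{ICC = (MSB - MSW) / (MSB + (k - 1) MSW)}
#' where MSB and MSW are the between- and within-subject mean squares of a
#' subjects x measurements table. The confidence interval uses the exact
#' F-distribution bounds; the p-value is the upper tail of
#' `F = MSB / MSW` on (n - 1, n(k - 1)) degrees of freedom. Rows containing
#' missing values are dropped listwise and counted.
#'
#' @param table Numeric matrix or data frame, one row per subject, one
#'   column per repeated measurement (k >= 2); at least 3 complete rows.
#' @param conf Confidence level for the interval. Default 0.95.
#' @return List with `icc`, `ci_low`, `ci_high`, `F`, `p`, `df1`, `df2`,
#'   `n` (complete subjects used), `k`, `n_dropped`.
#' @export
icc_oneway <- function(table, conf = 0.95) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (ncol(x) < 2) {
    stop("rps_format_error: ratings table needs >= 2 measurement columns",
         call. = FALSE)
  }
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3) {
    stop("rps_format_error: need at least 3 complete subjects, got ", n,
         call. = FALSE)
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((x - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    stop("rps_degenerate_error: zero between- and within-subject variance",
         call. = FALSE)
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  df1 <- n - 1
  df2 <- n * (k - 1)
  if (msw == 0) {
    f <- Inf; p <- 0; ci <- c(1, 1)
  } else {
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    alpha <- 1 - conf
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], F = f, p = p,
       df1 = df1, df2 = df2, n = n, k = k, n_dropped = n_dropped)
}

#' Mean and SD of paired right-minus-left differences
#'
#' @param right,left Numeric vectors of scores paired by participant
#'   (`right - left` convention).
#' @return List with `mean_diff`, `sd_diff` (sample SD), `n`.
#' @export
paired_stats <- function(right, left) {
  if (length(right) != length(left)) {
    stop("rps_format_error: right and left must be the same length",
         call. = FALSE)
  }
  ok <- is.finite(right) & is.finite(left)
  d <- right[ok] - left[ok]
  if (length(d) < 2) {
    stop("rps_format_error: need at least 2 complete pairs", call. = FALSE)
  }
  list(mean_diff = mean(d), sd_diff = stats::sd(d), n = length(d))
}

#' Build a subjects x 2 ratings table from long-format scores
#'
#' For `pairing = "eyes"` the two columns are a participant's right and
#' left eye; for `pairing = "repeats"` they are repeat acquisitions 1 and 2
#' of the same eye (subjects are then participant-eye combinations). Rows
#' with non-finite values, and subjects missing either measurement, are
#' dropped.
#'
#' @param scores Long-format data frame with `participant_id`, `eye`,
#'   `repeat_index` and the value column.
#' @param pairing `"eyes"` or `"repeats"`.
#' @param value_col Column holding the measurement. Default `"rps"`.
#' @return Numeric matrix with one row per subject and 2 columns.
#' @export
pair_table <- function(scores, pairing = c("eyes", "repeats"),
                       value_col = "rps") {
  pairing <- match.arg(pairing)
  if (pairing == "eyes") return(inter_eye_table(scores, value_col))
  s <- scores[is.finite(scores[[value_col]]) &
                scores$repeat_index %in% c(1, 2), , drop = FALSE]
  r1 <- s[s$repeat_index == 1, c("participant_id", "eye", value_col)]
  r2 <- s[s$repeat_index == 2, c("participant_id", "eye", value_col)]
  m <- merge(r1, r2, by = c("participant_id", "eye"))
  as.matrix(m[, c(paste0(value_col, ".x"), paste0(value_col, ".y"))])
}

# build a participants x 2 table of per-eye scores from long-format rows
inter_eye_table <- function(scores, value_col = "rps") {
  ok <- is.finite(scores[[value_col]])
  s <- scores[ok, , drop = FALSE]
  right <- s[s$eye == "right", c("participant_id", value_col)]
  left <- s[s$eye == "left", c("participant_id", value_col)]
  merged <- merge(right, left, by = "participant_id",
                  suffixes = c("_right", "_left"))
  as.matrix(merged[, c(paste0(value_col, "_right"),
                       paste0(value_col, "_left"))])
}

#' Compare (a,b)-only scoring with (L,a,b) scoring
#'
#' Scores the same cohort twice — once with the standard chromaticity-only
#' model and once with a three-component PCA on the full (L, a, b) triple,
#' projected on its first eigenvector — and reports the inter-eye
#' reliability of each. Discarding L removes per-image illumination
#' differences, so under illumination jitter the (a,b) pipeline is expected
#' to be at least as reliable as the (L,a,b) variant.
#'
#' @param scores Data frame with one row per eye and columns
#'   `participant_id`, `eye`, `L`, `a`, `b` (each participant with both
#'   eyes contributes to the ICC).
#' @param conf Confidence level passed to [icc_oneway()].
#' @return List with elements `ab` and `lab`, each containing the fitted
#'   model, per-row scores, the inter-eye `icc` result and `paired`
#'   difference stats; plus `n_pairs`.
#' @export
compare_lab_vs_ab <- function(scores, conf = 0.95) {
  stopifnot(all(c("participant_id", "eye", "L", "a", "b") %in% names(scores)))
  if (length(unique(scores$participant_id)) < 3) {
    stop("rps_format_error: need at least 3 participants", call. = FALSE)
  }
  run <- function(variables) {
    model <- rps_fit(scores, variables = variables)
    sc <- scores
    sc$rps <- rps_project(model, scores)
    tab <- inter_eye_table(sc)
    list(model = model, scores = sc,
         icc = icc_oneway(tab, conf = conf),
         paired = paired_stats(tab[, 1], tab[, 2]))
  }
  ab <- run(c("a", "b"))
  lab <- run(c("L", "a", "b"))
  list(ab = ab, lab = lab, n_pairs = ab$icc$n)
}
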