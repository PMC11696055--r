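validate_rps_model <- function(m) {
  stopifnot(inherits(m, "rps_model"))
  d <- length(m$variables)
  V <- m$eigenvectors
  if (!is.matrix(V) || any(dim(V) != d)) {
    stop("rps_schema_error: eigenvector matrix must be ", d, "x", d,
         call. = FALSE)
  }
  if (max(abs(V %*% t(V) - diag(d))) > 1e-8) {
    stop("rps_degenerate_model_error: eigenvector rows are not orthonormal",
         call. = FALSE)
  }
  if (is.unsorted(rev(m$eigenvalues)) || any(m$eigenvalues < 0)) {
    stop("rps_degenerate_model_error: eigenvalues must be descending and >= 0",
         call. = FALSE)
  }
  if (abs(sum(m$proportional_eigenvalues) - 1) > 1e-10) {
    stop("rps_degenerate_model_error: proportional eigenvalues must sum to 1",
         call. = FALSE)
  }
  if (!m$orientation %in% c(-1, 1)) {
    stop("rps_schema_error: orientation must be +1 or -1", call. = FALSE)
  }
  invisible(m)
}

as_point_matrix <- function(points, variables = c("a", "b")) {
  if (is.data.frame(points)) points <- as.matrix(points[, variables])
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  m <- as.matrix(points)
  if (ncol(m) != length(variables)) {
    stop("rps_format_error: expected ", length(variables),
         " columns (", paste(variables, collapse = ", "), "), got ", ncol(m),
         call. = FALSE)
  }
  colnames(m) <- variables
  m
}

#' Fit the RPS scale by principal component analysis
#'
#' Fits a full-rank PCA to the cohort's background chromaticities: the
#' points are mean-centred and the covariance (unbiased, divisor n - 1) is
#' eigendecomposed. Scores are later obtained by projecting on the
#' eigenvector with the greatest eigenvalue. The sign of that axis is
#' arbitrary in a PCA, so the model fixes an orientation such that scores
#' correlate positively with a* — redder/browner, i.e. more pigmented,
#' backgrounds score higher. If the a* correlation is numerically zero the
#' rule falls back to positive correlation with b*.
#'
#' The default is the two-variable (a, b) chromaticity model; passing
#' `variables = c("L", "a", "b")` fits the three-component variant used in
#' the reliability comparison.
#'
#' @param points n x d matrix or data frame of chromaticity points, n >= 3.
#' @param variables Column names defining the fitted space; default
#'   `c("a", "b")`.
#' @return An object of class `rps_model` with fields `mean`,
#'   `eigenvectors` (rows = components, descending eigenvalue),
#'   `eigenvalues`, `proportional_eigenvalues`, `orientation` and `n_fit`.
#' @export
rps_fit <- function(points, variables = c("a", "b")) {
  X <- as_point_matrix(points, variables)
  n <- nrow(X)
  if (n < 3) {
    stop("rps_fitting_error: need at least 3 points, got ", n, call. = FALSE)
  }
  if (anyNA(X) || !all(is.finite(X))) {
    stop("rps_fitting_error: non-finite chromaticity points", call. = FALSE)
  }
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)            # clip negative round-off
  if (sum(vals) <= 0 || vals[1] <= 0) {
    stop("rps_degenerate_model_error: zero-variance point cloud", call. = FALSE)
  }
  V <- t(e$vectors)                    # rows = components
  proj <- as.numeric(sweep(X, 2, mu) %*% V[1, ])
  orientation <- orient_sign(proj, X)
  m <- structure(list(
    variables = variables,
    mean = mu,
    eigenvectors = V,
    eigenvalues = vals,
    proportional_eigenvalues = vals / sum(vals),
    orientation = orientation,
    n_fit = n), class = "rps_model")
  validate_rps_model(m)
}

orient_sign <- function(proj, X) {
  for (col in c("a", "b")) {
    if (!col %in% colnames(X)) next
    r <- suppressWarnings(stats::cor(proj, X[, col]))
    if (is.finite(r) && abs(r) >= 1e-12) return(if (r >= 0) 1 else -1)
  }
  1
}

#' @export
print.rps_model <- function(x, ...) {
  cat(sprintf("<rps_model on (%s): n_fit=%d, proportional eigenvalues %s, orientation %+d>\n",
              paste(x$variables, collapse = ","), x$n_fit,
              paste(sprintf("%.3f", x$proportional_eigenvalues), collapse = "/"),
              x$orientation))
  invisible(x)
}

#' Project chromaticity points onto the RPS axis
#'
#' `score = orientation * <point - mean, first eigenvector>`: the signed
#' coordinate of the mean-centred point along the dominant eigenvector of
#' the fitting cohort. Applying a model fitted on one cohort to another
#' cohort's points — with no refit and no recentring — scores the new cohort
#' on the original scale (model transfer).
#'
#' @param model An [rps_fit()] model (possibly loaded with
#'   [load_rps_model()]).
#' @param points Vector, matrix or data frame of points in the model's
#'   variable space.
#' @return Numeric vector of RPS values.
#' @export
rps_project <- function(model, points) {
  validate_rps_model(model)
  X <- as_point_matrix(points, model$variables)
  if (anyNA(X) || !all(is.finite(X))) {
    stop("rps_projection_error: non-finite input point", call. = FALSE)
  }
  centred <- sweep(X, 2, model$mean)
  as.numeric(model$orientation * (centred %*% model$eigenvectors[1, ]))
}

#' Average RPS over a participant's gradable eyes
#'
#' @param scores Data frame with columns `participant_id` and `rps`; rows
#'   with non-finite `rps` (ungradable images) are dropped before
#'   averaging. A participant with a single gradable eye keeps that eye's
#'   value; participants with none are excluded.
#' @return Data frame with columns `participant_id`, `rps_mean`, `n_eyes`.
#' @export
mean_rps_per_participant <- function(scores) {
  stopifnot(all(c("participant_id", "rps") %in% names(scores)))
  ok <- is.finite(scores$rps)
  s <- scores[ok, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(participant_id = character(0), rps_mean = numeric(0),
                      n_eyes = integer(0)))
  }
  agg <- stats::aggregate(rps ~ participant_id, data = s, FUN = mean)
  cnt <- stats::aggregate(rps ~ participant_id, data = s, FUN = length)
  out <- data.frame(participant_id = agg$participant_id,
                    rps_mean = agg$rps,
                    n_eyes = as.integer(cnt$rps))
  out[match(unique(s$participant_id), out$participant_id), , drop = FALSE]
}

#' Standardise scores to z-units
#'
#' `(x - mean) / SD` with the sample SD (divisor n - 1).
#'
#' @param values Numeric vector, length >= 2, with nonzero spread.
#' @return Vector with mean 0 and SD 1.
#' @export
rps_zscore <- function(values) {
  if (length(values) < 2) {
    stop("rps_standardisation_error: need at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("rps_standardisation_error: zero spread", call. = FALSE)
  }
  (values - mean(values)) / s
}
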