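#' Beat similarity kernels
#'
#' Distance and similarity measures between two equal-length beat waveforms
#' `p` and `q`: the Euclidean distance (square root of the summed squared
#' differences; 0 means identical), the Mahalanobis distance
#' `sqrt((p - q) C^-1 (p - q)^T)` which whitens by a covariance `C` and
#' reduces to the Euclidean distance when `C` is the identity, and the
#' cosine similarity (1 means identical direction).
#'
#' @param p,q numeric waveforms of equal length (mV).
#' @param C symmetric positive-definite covariance matrix for
#'   [dist_mahalanobis].
#' @return A single numeric value: a distance in mV (`>= 0`) for the two
#'   distances, a similarity in `[-1, 1]` for [sim_cosine].
#' @name similarity-kernels
NULL

#' @rdname similarity-kernels
#' @export
dist_euclidean <- function(p, q) {
  check_pair(p, q)
  sqrt(sum((q - p)^2))
}

#' @rdname similarity-kernels
#' @export
dist_mahalanobis <- function(p, q, C) {
  check_pair(p, q)
  if (!is.matrix(C) || nrow(C) != length(p) || ncol(C) != length(p))
    stop("`C` must be a square matrix matching the waveform length",
         call. = FALSE)
  if (max(abs(C - t(C))) > 1e-8 * max(abs(C)))
    stop("`C` must be symmetric", call. = FALSE)
  d <- p - q
  sol <- tryCatch(solve(C, d), error = function(e) {
    stop(sprintf("covariance is numerically singular (condition number %.3g)",
                 kappa(C)), call. = FALSE)
  })
  val <- sum(d * sol)
  if (val < 0 && val > -1e-10) val <- 0
  if (val < 0)
    stop("covariance is not positive definite", call. = FALSE)
  sqrt(val)
}

#' @rdname similarity-kernels
#' @export
sim_cosine <- function(p, q) {
  check_pair(p, q)
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0)
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  sum(p * q) / (np * nq)
}

check_pair <- function(p, q) {
  if (length(p) != length(q))
    stop("waveforms must have equal length", call. = FALSE)
  invisible(TRUE)
}

#' Convert a distance to a percentage similarity
#'
#' Maps a non-negative distance `d` to `100 * scale / (scale + d)`: 100% at
#' zero distance, 50% at `d = scale`, strictly decreasing in `d`. The scale
#' is a reference distance; a robust default is the median distance of the
#' set under comparison.
#'
#' @param d non-negative distance (vectorized).
#' @param scale positive reference distance.
#' @return Percentage in `(0, 100]`.
#' @export
to_percent <- function(d, scale) {
  if (any(d < 0)) stop("`d` must be non-negative", call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  100 * scale / (scale + d)
}

#' Map a cosine similarity to a percentage
#'
#' Affine map of `[-1, 1]` onto `[0, 100]`.
#'
#' @param s cosine similarity values in `[-1, 1]`.
#' @return Percentage in `[0, 100]`.
#' @export
cosine_percent <- function(s) {
  if (any(s < -1 - 1e-12) || any(s > 1 + 1e-12))
    stop("cosine similarity must lie in [-1, 1]", call. = FALSE)
  50 * (pmin(pmax(s, -1), 1) + 1)
}

#' Estimate a beat covariance with diagonal loading
#'
#' Sample covariance of a cycle set with a ridge `eps * trace / dim` added
#' to the diagonal so the matrix is invertible even when there are fewer
#' beats than samples per beat.
#'
#' @param cycles list of equal-length [ecg_cycle] objects (or a numeric
#'   matrix, one row per beat).
#' @param eps relative ridge weight.
#' @return Symmetric positive-definite covariance matrix.
#' @export
estimate_covariance <- function(cycles, eps = 1e-6) {
  m <- if (is.matrix(cycles)) cycles else cycles_to_matrix(cycles)
  C <- stats::cov(m)
  tr <- sum(diag(C))
  if (tr <= 0) tr <- 1
  ridge <- max(eps * tr / ncol(m), 1e-12)
  C + diag(ridge, ncol(m))
}
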