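# Subtractive clustering: density-ranked selection of the number and
# initial positions of the RBF hidden units.

# pairwise squared Euclidean distances between rows of a and rows of b
.sq_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Subtractive-clustering configuration
#'
#' @param alpha neighborhood radius in normalized-feature units; controls
#'   how far a point's density reaches. Default 0.5.
#' @param mu suppression ratio; the revision radius is `beta = mu * alpha`
#'   (conventionally 1.5, which keeps accepted centers apart).
#' @param delta stopping factor in (0, 1): selection stops the first time a
#'   candidate's density falls below `delta` times the first center's.
#' @return A `sc_config` list.
#' @export
sc_config <- function(alpha = 0.5, mu = 1.5, delta = 0.15) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.numeric(mu) || mu <= 1) stop("mu must be > 1")
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop("delta must lie strictly in (0, 1)")
  structure(list(alpha = alpha, mu = mu, delta = delta), class = "sc_config")
}

#' Data density of every point
#'
#' `D_i = sum_j exp(-||X_i - X_j||^2 / (alpha/2)^2)`, the self term
#' included, so every density is at least 1.
#'
#' @param points numeric matrix, one row per point.
#' @param alpha neighborhood radius (> 0).
#' @return numeric vector of densities.
#' @export
sc_densities <- function(points, alpha) {
  points <- as.matrix(points)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a single value > 0")
  if (nrow(points) < 1L) stop("need at least one point")
  rowSums(exp(-.sq_dist(points, points) / (alpha / 2)^2))
}

#' Subtract a selected center's influence from the density field
#'
#' `D_i <- D_i - D* exp(-||X_i - X*||^2 / (beta/2)^2)`, floored at zero.
#' The chosen center's own density becomes exactly 0.
#'
#' @param densities current density vector.
#' @param points point matrix the densities refer to.
#' @param center_index row index of the just-selected center.
#' @param d_star density of that center at selection time.
#' @param beta suppression radius (`mu * alpha`).
#' @return revised density vector.
#' @export
sc_revise_densities <- function(densities, points, center_index, d_star, beta) {
  points <- as.matrix(points)
  if (center_index < 1L || center_index > nrow(points))
    stop("center_index out of range")
  if (beta <= 0) stop("beta must be > 0")
  d2 <- .sq_dist(points, points[center_index, , drop = FALSE])[, 1]
  pmax(densities - d_star * exp(-d2 / (beta / 2)^2), 0)
}

#' Subtractive clustering
#'
#' Iteratively selects the highest-density point as a center, subtracts its
#' influence, and repeats until the candidate's density drops below
#' `delta` times the first selection's density (the triggering candidate
#' is not kept). Ties in the argmax are broken by
#' the lowest row index, so the procedure is fully deterministic and
#' permutation-equivariant up to that documented rule.
#'
#' @param points numeric matrix (rows = points, typically normalized
#'   (t,x,y,z) features).
#' @param config an [sc_config()].
#' @return list with `centers` (matrix, selection order), `indices` (rows of
#'   `points` selected), `selection_densities` (density of each center when
#'   chosen, non-increasing), `first_density`, `n_centers`, and the final
#'   `densities` vector.
#' @export
subtractive_cluster <- function(points, config = sc_config()) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 1L) stop("need at least one point")
  stopifnot(inherits(config, "sc_config"))
  beta <- config$mu * config$alpha
  D <- sc_densities(points, config$alpha)
  idx <- integer(0)
  dsel <- numeric(0)
  d1 <- NA_real_
  repeat {
    i_star <- which.max(D)         # which.max takes the lowest index on ties
    d_star <- D[i_star]
    if (length(idx) == 0L) {
      d1 <- d_star                 # the first center is always kept
    } else if (length(idx) >= m || d_star / d1 < config$delta) {
      break
    }
    idx <- c(idx, i_star)
    dsel <- c(dsel, d_star)
    D <- sc_revise_densities(D, points, i_star, d_star, beta)
  }
  list(centers = points[idx, , drop = FALSE], indices = idx,
       selection_densities = dsel, first_density = d1,
       n_centers = length(idx), densities = D)
}

#' Calibrate the neighborhood radius to a target cluster count
#'
#' The cluster count is a step function of `alpha` and not guaranteed
#' monotone, so a scan over 200 log-spaced candidates in
#' (1e-3 d_max, 2 d_max] locates radii achieving `target_k`, then bisection
#' pushes the largest such radius up against its boundary. Used to
#' reproduce a reported hidden-unit count when the radius itself was never
#' published.
#'
#' @param points numeric matrix of (normalized) points.
#' @param target_k desired number of centers, `1 <= target_k <=` number of
#'   distinct points.
#' @param config an [sc_config()]; its `alpha` is ignored.
#' @param n_scan number of log-spaced scan candidates.
#' @return the calibrated `alpha` (largest radius found with exactly
#'   `target_k` centers).
#' @export
calibrate_alpha <- function(points, target_k, config = sc_config(),
                            n_scan = 200L) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (length(target_k) != 1L || target_k < 1L || target_k > n_distinct)
    stop("target_k must lie in [1, ", n_distinct, "] (distinct points)")
  d_max <- sqrt(max(.sq_dist(points, points)))
  if (d_max == 0) {
    if (target_k == 1L) return(1)
    stop("all points coincide; only target_k = 1 is achievable")
  }
  count_at <- function(a)
    subtractive_cluster(points, sc_config(a, config$mu, config$delta))$n_centers
  cand <- exp(seq(log(1e-3 * d_max), log(2 * d_max), length.out = n_scan))
  counts <- vapply(cand, count_at, integer(1))
  hit <- which(counts == target_k)
  if (length(hit) == 0L)
    stop("calibration error: no radius in the scan yields ", target_k,
         " centers; achievable counts: ",
         paste(sort(unique(counts)), collapse = ", "))
  i <- max(hit)
  lo <- cand[i]
  hi <- if (i < length(cand)) cand[i + 1L] else 2 * d_max
  for (iter in seq_len(40L)) {
    mid <- (lo + hi) / 2
    if (count_at(mid) == target_k) lo <- mid else hi <- mid
  }
  lo
}
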