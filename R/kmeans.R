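# Lloyd-style K-means used to refine the subtractive-clustering centers.
# Written in-package because the hybrid path needs a deterministic,
# seed-free iteration with a "retain previous center" empty-cluster policy.

#' Nearest-center assignment
#'
#' Each point is labeled with the index of its nearest center by Euclidean
#' distance; ties go to the lowest center index.
#'
#' @param points numeric matrix, one row per point.
#' @param centers numeric matrix, one row per center.
#' @return integer vector of labels in `1..nrow(centers)`.
#' @export
assign_clusters <- function(points, centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("need at least one center")
  d2 <- .sq_dist(as.matrix(points), centers)
  max.col(-d2, ties.method = "first")
}

#' Centroid update
#'
#' Each center moves to the mean of its members; a cluster with no members
#' keeps its previous center (re-seeding would inject randomness into an
#' otherwise deterministic pipeline).
#'
#' @param points numeric matrix.
#' @param labels integer labels from [assign_clusters()].
#' @param centers current center matrix (supplies the value for empty
#'   clusters and the cluster count).
#' @return updated center matrix.
#' @export
update_centers <- function(points, labels, centers) {
  points <- as.matrix(points); centers <- as.matrix(centers)
  k <- nrow(centers)
  if (any(labels < 1L | labels > k)) stop("label out of range 1..", k)
  out <- centers
  for (j in seq_len(k)) {
    members <- labels == j
    if (any(members)) {
      out[j, ] <- colMeans(points[members, , drop = FALSE])
    } else {
      warning("cluster ", j, " is empty; keeping its previous center")
    }
  }
  out
}

#' K-means refinement (Lloyd iteration)
#'
#' Alternates [assign_clusters()] and [update_centers()] from the supplied
#' initial centers until the largest center displacement falls below `tol`
#' or `max_iter` is reached. Deterministic given the initialization.
#'
#' @param points numeric matrix.
#' @param init initial center matrix (e.g. the subtractive-clustering
#'   selection).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the max center displacement, in the
#'   same (normalized) units as `points`.
#' @return list with `centers`, `labels`, `counts`, `sse` (within-cluster
#'   sum of squares), `iterations`, `converged`, and `sse_trace` (SSE after
#'   each assignment, non-increasing).
#' @export
kmeans_refine <- function(points, init, max_iter = 300L, tol = 1e-9) {
  points <- as.matrix(points)
  centers <- as.matrix(init)
  if (nrow(centers) < 1L) stop("init must contain at least one center")
  if (any(!is.finite(centers))) stop("init centers must be finite")
  sse_trace <- numeric(0)
  labels <- assign_clusters(points, centers)
  converged <- FALSE
  iter <- 0L
  repeat {
    sse_trace <- c(sse_trace, .wcss(points, labels, centers))
    if (iter >= max_iter) break
    iter <- iter + 1L
    new_centers <- suppressWarnings(update_centers(points, labels, centers))
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    labels <- assign_clusters(points, centers)
    if (shift < tol) { converged <- TRUE; break }
  }
  counts <- tabulate(labels, nbins = nrow(centers))
  list(centers = centers, labels = labels, counts = counts,
       sse = .wcss(points, labels, centers), iterations = iter,
       converged = converged, sse_trace = c(sse_trace,
                                            .wcss(points, labels, centers)))
}

.wcss <- function(points, labels, centers) {
  sum((points - centers[labels, , drop = FALSE])^2)
}
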