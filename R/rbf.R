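# Gaussian RBF network core: shared width, design matrix, least-squares
# weights, prediction and text-file persistence.

#' Shared Gaussian width from the center geometry
#'
#' `sigma = d_max / sqrt(2 n)` where `d_max` is the maximum pairwise
#' distance between the `n` hidden-unit centers — the classical heuristic
#' that keeps the basis functions neither needle-sharp nor indistinct.
#'
#' @param centers numeric matrix of hidden-unit centers.
#' @return the width `sigma` (> 0).
#' @export
rbf_width <- function(centers) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 2L)
    stop("degenerate centers: need >= 2 hidden units to derive a width; ",
         "supply sigma explicitly")
  d_max <- sqrt(max(.sq_dist(centers, centers)))
  if (d_max == 0)
    stop("degenerate centers: all hidden units coincide (d_max = 0); ",
         "supply sigma explicitly")
  d_max / sqrt(2 * n)
}

#' Gaussian design matrix
#'
#' `Phi[j, i] = exp(-||x_j - c_i||^2 / (2 sigma^2))`; every entry lies in
#' (0, 1].
#'
#' @param points numeric matrix of evaluation points (rows).
#' @param centers numeric matrix of hidden-unit centers.
#' @param sigma shared width (> 0).
#' @return `nrow(points) x nrow(centers)` matrix.
#' @export
rbf_design <- function(points, centers, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0")
  exp(-.sq_dist(as.matrix(points), as.matrix(centers)) / (2 * sigma^2))
}

#' Least-squares output weights
#'
#' Minimum-norm least-squares solution of `Phi w = y` via the SVD
#' pseudo-inverse (singular values below `1e-10 * max(sv)` truncated).
#' With `ridge > 0` the damped normal equations
#' `(Phi'Phi + ridge I) w = Phi'y` are solved instead.
#'
#' @param Phi design matrix.
#' @param y response vector (DO, mg/L).
#' @param ridge ridge penalty (>= 0, default 0).
#' @return weight vector of length `ncol(Phi)`.
#' @export
rbf_weights <- function(Phi, y, ridge = 0) {
  Phi <- as.matrix(Phi)
  if (nrow(Phi) != length(y)) stop("nrow(Phi) must equal length(y)")
  if (ridge < 0) stop("ridge must be >= 0")
  if (ridge > 0) {
    w <- solve(crossprod(Phi) + diag(ridge, ncol(Phi)), crossprod(Phi, y))
    w <- drop(w)
  } else {
    sv <- svd(Phi)
    keep <- sv$d > 1e-10 * max(sv$d)
    w <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
    w <- drop(w)
  }
  if (any(!is.finite(w)))
    stop("least-squares solution is not finite; the Gaussian system is ",
         "ill-conditioned — try ridge > 0")
  w
}

#' Assemble an RBF interpolation model
#'
#' @param centers hidden-unit centers in normalized feature space.
#' @param sigma shared Gaussian width.
#' @param weights output-layer weights (length `nrow(centers)`, plus one
#'   trailing bias weight if `bias = TRUE`).
#' @param normalizer the `do_normalizer` applied to raw (t,x,y,z) queries
#'   before distances are computed.
#' @param bias whether an all-ones bias column was appended at fit time.
#' @return An object of class `rbf_model`.
#' @export
rbf_model <- function(centers, sigma, weights, normalizer, bias = FALSE) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (length(weights) != n + as.integer(bias))
    stop("weights length must match number of centers (+ bias)")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (sigma <= 0) stop("sigma must be > 0")
  d_max <- if (n >= 2L) sqrt(max(.sq_dist(centers, centers))) else 0
  structure(list(centers = centers, sigma = sigma,
                 weights = as.numeric(weights), bias = bias,
                 normalizer = normalizer, n = n, d_max = d_max),
            class = "rbf_model")
}

#' @export
print.rbf_model <- function(x, ...) {
  cat("Gaussian RBF model: ", x$n, " hidden units, sigma = ",
      format(x$sigma, digits = 6), ", d_max = ",
      format(x$d_max, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Predict dissolved oxygen at raw query coordinates
#'
#' Queries are given in raw units (minutes, meters); the model's stored
#' normalizer is applied before the Gaussian responses are combined
#' linearly with the fitted weights.
#'
#' @param object an `rbf_model`.
#' @param newdata sample set, data.frame with t/x/y/z, 4-column matrix, or a
#'   single length-4 vector.
#' @param ... unused.
#' @return numeric vector of DO predictions (mg/L).
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  q <- as_feature_matrix(newdata)
  if (any(!is.finite(q))) stop("query coordinates must be finite")
  qn <- normalize_features(object$normalizer, q)
  Phi <- rbf_design(qn, object$centers, object$sigma)
  if (object$bias) Phi <- cbind(Phi, 1)
  unname(drop(Phi %*% object$weights))
}

# numbers are serialized as %.17g strings so a written model re-reads
# bit-exactly
.num_out <- function(v) sprintf("%.17g", as.numeric(v))
.num_in <- function(s) as.numeric(s)

#' Write / read an RBF model as a flat JSON text file
#'
#' Numeric fields are stored as 17-significant-digit decimal strings, which
#' round-trip IEEE doubles exactly, so `read_rbf_model(write_rbf_model(m))`
#' reproduces the model bit-for-bit and repeated writes of the same model
#' are byte-identical.
#'
#' @param model an `rbf_model`.
#' @param path output (input) file.
#' @return `path`, invisibly (the model for `read_rbf_model`).
#' @export
write_rbf_model <- function(model, path) {
  stopifnot(inherits(model, "rbf_model"))
  nm <- model$normalizer
  obj <- list(
    type = "pondrbf/rbf_model",
    n = model$n,
    dim = ncol(model$centers),
    sigma = .num_out(model$sigma),
    bias = model$bias,
    centers = .num_out(t(model$centers)),  # row-major center coordinates
    weights = .num_out(model$weights),
    normalizer = list(method = nm$method, offset = .num_out(nm$offset),
                      scale = .num_out(nm$scale),
                      degenerate = as.logical(nm$degenerate)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_rbf_model
#' @export
read_rbf_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$type, "pondrbf/rbf_model"))
    stop("'", path, "' is not a pondrbf model file")
  centers <- matrix(.num_in(obj$centers), nrow = obj$n, ncol = obj$dim,
                    byrow = TRUE, dimnames = list(NULL, FEATURES))
  norm <- structure(list(
    offset = stats::setNames(.num_in(obj$normalizer$offset), FEATURES),
    scale = stats::setNames(.num_in(obj$normalizer$scale), FEATURES),
    degenerate = stats::setNames(as.logical(obj$normalizer$degenerate),
                                 FEATURES),
    method = obj$normalizer$method), class = "do_normalizer")
  rbf_model(centers, .num_in(obj$sigma), .num_in(obj$weights), norm,
            bias = isTRUE(obj$bias))
}
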