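# Comparison interpolators: standard RBF with a trial hidden-unit count,
# inverse distance weighting, and ordinary Kriging with a spherical
# variogram.

#' Standard RBF baseline with a trial hidden-unit count
#'
#' The classical two-stage fit: K-means with seeded random initialization
#' (k distinct training rows drawn without replacement; `restarts` runs,
#' best within-cluster SSE kept) positions the centers, then the shared
#' width comes from the center geometry and the weights from least
#' squares. Reproducible for a fixed `seed`.
#'
#' @param train a [sample_set()].
#' @param k number of hidden units, `1 <= k <= nrow(train)`.
#' @param seed integer seed for the random initializations.
#' @param restarts number of random restarts (default 10).
#' @param normalize min-max normalize features (default TRUE).
#' @param bias include an intercept column, as in [sc_kmeans_rbf()]
#'   (default TRUE; keeps the baseline's output layer identical to the
#'   hybrid's so the comparison isolates the center-selection strategy).
#' @param ridge ridge penalty for the weight solve.
#' @return An [rbf_model()].
#' @export
standard_rbf_fit <- function(train, k, seed = 1L, restarts = 10L,
                             normalize = TRUE, bias = TRUE, ridge = 0) {
  n <- nrow(train)
  if (length(k) != 1L || k < 1L || k > n)
    stop("k must satisfy 1 <= k <= ", n)
  norm <- if (normalize) fit_normalizer(train) else identity_normalizer()
  pts <- normalize_features(norm, train)
  upts <- unique(pts)
  if (k > nrow(upts))
    stop("k exceeds the number of distinct training points (", nrow(upts), ")")
  best <- NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (r in seq_len(restarts)) {
    init <- upts[sample.int(nrow(upts), k), , drop = FALSE]
    km <- kmeans_refine(pts, init)
    if (is.null(best) || km$sse < best$sse) best <- km
  }
  width <- rbf_width(best$centers)
  Phi <- rbf_design(pts, best$centers, width)
  if (bias) Phi <- cbind(Phi, 1)
  w <- rbf_weights(Phi, train$do, ridge = ridge)
  rbf_model(best$centers, width, w, norm, bias = bias)
}

#' Inverse-distance-weighted interpolator
#'
#' `yhat = sum(y_i d_i^-p) / sum(d_i^-p)` with `d_i` the Euclidean
#' distance in (normalized) (t,x,y,z) space. A query coinciding with a
#' sample returns that sample's value exactly; predictions are bounded by
#' the observed range.
#'
#' @param train a [sample_set()].
#' @param power inverse-distance exponent p (> 0, default 2).
#' @param normalize min-max normalize features (default TRUE).
#' @return An `idw_model` usable with `predict()` / [evaluate_model()].
#' @export
idw_fit <- function(train, power = 2, normalize = TRUE) {
  if (!is.numeric(power) || power <= 0) stop("power must be > 0")
  if (nrow(train) < 1L) stop("need at least one training point")
  norm <- if (normalize) fit_normalizer(train) else identity_normalizer()
  structure(list(points = normalize_features(norm, train), y = train$do,
                 power = power, normalizer = norm),
            class = "idw_model")
}

#' @export
predict.idw_model <- function(object, newdata, ...) {
  q <- normalize_features(object$normalizer, as_feature_matrix(newdata))
  d2 <- .sq_dist(q, object$points)
  unname(apply(d2, 1, function(row) {
    hit <- row <= 0
    if (any(hit)) return(mean(object$y[hit]))
    w <- row^(-object$power / 2)  # d^-p on squared distances
    sum(w * object$y) / sum(w)
  }))
}

#' Spherical variogram value
#'
#' `gamma(h) = nugget + psill * (1.5 h/a - 0.5 (h/a)^3)` for `h < a`,
#' `nugget + psill` beyond the range `a`, and 0 at `h = 0`.
#'
#' @param h distances (m).
#' @param nugget nugget variance.
#' @param psill partial sill (sill - nugget).
#' @param range variogram range a (m).
#' @return semivariance at each `h`.
#' @export
spherical_gamma <- function(h, nugget, psill, range) {
  g <- ifelse(h >= range, nugget + psill,
              nugget + psill * (1.5 * h / range - 0.5 * (h / range)^3))
  ifelse(h <= 0, 0, g)
}

#' Empirical semivariogram
#'
#' Pairwise semivariances `0.5 (y_i - y_j)^2` averaged in distance bins of
#' width `lag` up to `n_lags * lag`, over raw-meter (x, y, z) coordinates.
#'
#' @param coords numeric matrix of spatial coordinates in meters.
#' @param y observed values.
#' @param lag bin width (m).
#' @param n_lags number of bins.
#' @return data.frame with bin midpoint `h`, semivariance `gamma`, pair
#'   count `npairs` (empty bins dropped).
#' @export
empirical_variogram <- function(coords, y, lag = 100, n_lags = 20L) {
  if (lag <= 0) stop("lag must be > 0")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need >= 3 points for a variogram")
  d <- as.vector(stats::dist(coords))
  ij <- utils::combn(n, 2L)
  sv <- 0.5 * (y[ij[1, ]] - y[ij[2, ]])^2
  bin <- ceiling(d / lag)
  keep <- bin >= 1L & bin <= n_lags & d > 0
  bin <- bin[keep]; sv <- sv[keep]
  if (length(sv) == 0L) stop("no point pairs fall inside the lag bins")
  agg_g <- tapply(sv, bin, mean)
  agg_n <- tapply(sv, bin, length)
  bins <- as.integer(names(agg_g))
  data.frame(h = (bins - 0.5) * lag, gamma = as.numeric(agg_g),
             npairs = as.integer(agg_n))
}

#' Fit a spherical variogram model
#'
#' Weighted least squares (weights = pair counts) of the spherical model to
#' the empirical semivariogram. With fewer than 3 non-empty bins the model
#' cannot be identified; a pragmatic default (nugget 0, sill = series
#' variance, range = max pair distance) is returned with `fitted = FALSE`.
#'
#' @param train a [sample_set()] (kriging works in raw meters over x, y, z).
#' @param lag bin width in meters (default 100).
#' @param n_lags number of bins (default 20).
#' @return A `variogram_model` list: `nugget`, `sill`, `range`, `lag`,
#'   `n_lags`, `fitted`, and the `empirical` table.
#' @export
fit_variogram <- function(train, lag = 100, n_lags = 20L) {
  coords <- as.matrix(train[, c("x", "y", "z")])
  emp <- empirical_variogram(coords, train$do, lag = lag, n_lags = n_lags)
  d_max <- max(stats::dist(coords))
  vy <- stats::var(train$do)
  if (nrow(emp) < 3L) {
    vm <- list(nugget = 0, sill = max(vy, mean(emp$gamma)), range = d_max,
               fitted = FALSE)
  } else {
    obj <- function(p) {
      g <- spherical_gamma(emp$h, p[1], p[2], p[3])
      sum(emp$npairs * (g - emp$gamma)^2)
    }
    fit <- stats::optim(c(0, max(vy, 1e-8), d_max / 2), obj,
                        method = "L-BFGS-B",
                        lower = c(0, 1e-10, 1e-6 + 0 * d_max),
                        upper = c(Inf, Inf, 2 * d_max))
    vm <- list(nugget = fit$par[1], sill = fit$par[1] + fit$par[2],
               range = fit$par[3], fitted = TRUE)
  }
  structure(c(vm, list(lag = lag, n_lags = n_lags, empirical = emp)),
            class = "variogram_model")
}

#' Ordinary-kriging interpolator
#'
#' Fits (or accepts) a spherical variogram, then solves the ordinary-
#' kriging system per query over raw-meter (x, y, z) coordinates with the
#' unbiasedness constraint (weights sum to 1). Duplicated coordinates are
#' averaged first (the kriging matrix is otherwise singular). Time is not
#' part of the kriging distance: all samples are treated as one window.
#'
#' @param train a [sample_set()].
#' @param vgm optional pre-fitted `variogram_model`.
#' @param lag,n_lags passed to [fit_variogram()] when `vgm` is NULL.
#' @return A `kriging_model` usable with `predict()` / [evaluate_model()].
#' @export
kriging_fit <- function(train, vgm = NULL, lag = 100, n_lags = 20L) {
  if (is.null(vgm)) vgm <- fit_variogram(train, lag = lag, n_lags = n_lags)
  coords <- as.matrix(train[, c("x", "y", "z")])
  y <- train$do
  key <- apply(coords, 1, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate sample coordinates averaged before kriging")
    grp <- match(key, unique(key))
    coords <- as.matrix(stats::aggregate(coords, list(grp), mean)[, -1])
    y <- as.numeric(tapply(y, grp, mean))
  }
  n <- nrow(coords)
  G <- spherical_gamma(as.matrix(stats::dist(coords)), vgm$nugget,
                       vgm$sill - vgm$nugget, vgm$range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  structure(list(coords = coords, y = y, vgm = vgm, A = A),
            class = "kriging_model")
}

#' @export
predict.kriging_model <- function(object, newdata, se = FALSE, ...) {
  q <- as_feature_matrix(newdata)[, c("x", "y", "z"), drop = FALSE]
  vgm <- object$vgm
  n <- length(object$y)
  out <- apply(q, 1, function(p) {
    h0 <- sqrt(colSums((t(object$coords) - p)^2))
    g0 <- spherical_gamma(h0, vgm$nugget, vgm$sill - vgm$nugget, vgm$range)
    sol <- solve(object$A, c(g0, 1))
    lambda <- sol[seq_len(n)]
    c(sum(lambda * object$y), sum(lambda * g0) + sol[n + 1L])
  })
  if (se) list(pred = unname(out[1, ]), var = unname(pmax(out[2, ], 0)))
  else unname(out[1, ])
}

#' Kriging weights for a single query (diagnostic)
#'
#' @param object a `kriging_model`.
#' @param point length-3 vector (x, y, z) in meters.
#' @return numeric weight vector summing to 1.
#' @export
kriging_weights <- function(object, point) {
  vgm <- object$vgm
  h0 <- sqrt(colSums((t(object$coords) - point)^2))
  g0 <- spherical_gamma(h0, vgm$nugget, vgm$sill - vgm$nugget, vgm$range)
  sol <- solve(object$A, c(g0, 1))
  sol[seq_len(length(object$y))]
}
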