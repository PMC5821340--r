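# The SC-K-means-RBF hybrid: subtractive clustering proposes the number
# and position of the hidden units, K-means refines them, the width comes
# from the refined center geometry and the output weights from least
# squares. Entirely deterministic: no stage draws a random number.

#' Fit the SC-K-means-RBF interpolation model
#'
#' Pipeline: (1) min-max normalize the (t, x, y, z) features over the
#' training set; (2) subtractive clustering selects the cluster count `N_S`
#' and initial centers `C_S` (when `target_k` is given, the neighborhood
#' radius is first calibrated with [calibrate_alpha()] to yield exactly
#' `target_k` centers); (3) K-means seeded at `C_S` refines the centers;
#' (4) the shared width is `d_max / sqrt(2 n)` over the refined centers;
#' (5) the output weights solve the Gaussian least-squares system.
#'
#' By default an intercept (bias) column accompanies the Gaussian basis:
#' dissolved oxygen has a physical background level of roughly 2 mg/L that
#' a sum of localized Gaussians cannot represent, and without the
#' intercept the training error is several times the sensor noise.
#' `bias = FALSE` restores the pure Gaussian expansion.
#'
#' @param train a [sample_set()] with at least 2 rows.
#' @param config an [sc_config()] (neighborhood radius, suppression ratio,
#'   stopping factor).
#' @param target_k optional hidden-unit count to calibrate the radius to.
#' @param normalize min-max normalize features (default TRUE); FALSE
#'   computes every distance in raw minutes/meters.
#' @param bias include an intercept column in the output layer (default
#'   TRUE).
#' @param sigma optional manual width overriding the heuristic (required
#'   when only one center survives).
#' @param ridge optional ridge penalty for the weight solve.
#' @param max_iter,tol K-means iteration controls.
#' @return list of class `sc_kmeans_rbf` with `model` (an [rbf_model()])
#'   and `report` (hidden-unit count, initial and refined centers, width,
#'   training metrics, configuration echo).
#' @export
sc_kmeans_rbf <- function(train, config = sc_config(), target_k = NULL,
                          normalize = TRUE, bias = TRUE, sigma = NULL,
                          ridge = 0, max_iter = 300L, tol = 1e-9) {
  if (nrow(train) < 2L) stop("stage tabular_io: need >= 2 training samples")
  norm <- if (normalize) fit_normalizer(train) else identity_normalizer()
  pts <- normalize_features(norm, train)
  y <- train$do

  if (!is.null(target_k)) {
    alpha <- calibrate_alpha(pts, target_k, config)
    config <- sc_config(alpha, config$mu, config$delta)
  }
  sc <- subtractive_cluster(pts, config)

  km <- kmeans_refine(pts, sc$centers, max_iter = max_iter, tol = tol)
  if (!km$converged)
    warning("stage kmeans_refine: not converged within ", max_iter,
            " iterations")

  width <- if (!is.null(sigma)) sigma else rbf_width(km$centers)
  Phi <- rbf_design(pts, km$centers, width)
  if (bias) Phi <- cbind(Phi, 1)
  w <- rbf_weights(Phi, y, ridge = ridge)
  model <- rbf_model(km$centers, width, w, norm, bias = bias)

  train_metrics <- metrics_report(y, predict(model, train))
  report <- list(n_clusters = sc$n_centers, initial_centers = sc$centers,
                 refined_centers = km$centers, sigma = width,
                 kmeans_iterations = km$iterations,
                 kmeans_converged = km$converged,
                 training_metrics = train_metrics,
                 config = config, normalized = normalize,
                 target_k = target_k)
  structure(list(model = model, report = report), class = "sc_kmeans_rbf")
}

#' @export
print.sc_kmeans_rbf <- function(x, ...) {
  cat("SC-K-means-RBF fit: ", x$report$n_clusters, " hidden units, sigma = ",
      format(x$report$sigma, digits = 6), "\n", sep = "")
  cat("training: ")
  print(x$report$training_metrics)
  invisible(x)
}

#' @export
predict.sc_kmeans_rbf <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Evaluate a fitted interpolator on a test sample set
#'
#' Works for any model with a `predict(model, samples)` method returning
#' DO values (`rbf_model`, `sc_kmeans_rbf`, `idw_model`, `kriging_model`).
#'
#' @param model fitted interpolator.
#' @param test a [sample_set()].
#' @return A [metrics_report()]. With a single test point, R is undefined
#'   and reported as `NaN` with a warning.
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test) < 1L) stop("test set is empty")
  metrics_report(test$do, predict(model, test))
}
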