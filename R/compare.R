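# Side-by-side comparison of the hybrid interpolator with the baselines,
# and the summary arithmetic over such a table.

#' Compare the hybrid model against the three baselines
#'
#' Fits SC-K-means-RBF, standard RBF at each trial hidden-unit count, IDW
#' and ordinary Kriging on `train`, evaluates on `test`, and lays the four
#' statistics out with one column per model: hybrid training, hybrid
#' testing, one standard-RBF column per `rbf_k`, IDW and Kriging.
#'
#' @param train,test [sample_set()]s (positional split of one campaign).
#' @param rbf_k trial hidden-unit counts for the standard-RBF baseline.
#' @param target_k optional calibrated hidden-unit count for the hybrid fit.
#' @param config an [sc_config()].
#' @param seed seed for the standard-RBF random initializations.
#' @param idw_power IDW exponent.
#' @param lag,n_lags variogram binning (meters / count).
#' @return A `comparison_table`: data.frame with rownames RMSE/MAE/R/D and
#'   one column per model, plus a `hidden_units` attribute.
#' @export
compare_models <- function(train, test, rbf_k = c(10, 15, 20, 21, 22),
                           target_k = NULL, config = sc_config(),
                           seed = 1L, idw_power = 2, lag = 100,
                           n_lags = 20L) {
  hy <- sc_kmeans_rbf(train, config = config, target_k = target_k)
  cols <- list(
    `SC-K-means-RBF (training)` = hy$report$training_metrics,
    `SC-K-means-RBF (testing)` = evaluate_model(hy, test))
  units <- c(hy$report$n_clusters, hy$report$n_clusters)
  for (k in rbf_k) {
    m <- standard_rbf_fit(train, k, seed = seed)
    cols[[paste0("Standard RBF (", k, ")")]] <- evaluate_model(m, test)
    units <- c(units, k)
  }
  cols[["IDW"]] <- evaluate_model(idw_fit(train, power = idw_power), test)
  cols[["Kriging"]] <- evaluate_model(
    kriging_fit(train, lag = lag, n_lags = n_lags), test)
  units <- c(units, NA, NA)
  tab <- as.data.frame(lapply(cols, function(m)
    c(RMSE = m$rmse, MAE = m$mae, R = m$r, D = m$d)),
    check.names = FALSE, optional = TRUE)
  rownames(tab) <- c("RMSE", "MAE", "R", "D")
  structure(tab, hidden_units = units,
            class = c("comparison_table", "data.frame"))
}

#' Error statistics from the original crab-pond field deployment
#'
#' The published benchmark for this method: four statistics for the hybrid
#' model (training and testing on a 51/10 positional split of 61 samples),
#' the standard RBF at five trial hidden-unit counts, IDW and Kriging.
#' Used as the reference for summary arithmetic and regression checks.
#'
#' @return A `comparison_table` in the same layout as [compare_models()].
#' @export
reference_error_stats <- function() {
  tab <- data.frame(
    `SC-K-means-RBF (training)` = c(0.3072, 0.2000, 0.9309, 0.9998),
    `SC-K-means-RBF (testing)`  = c(0.4929, 0.3484, 0.8098, 0.9879),
    `Standard RBF (10)`         = c(0.7022, 0.4841, 0.5568, 0.9725),
    `Standard RBF (15)`         = c(0.6165, 0.4152, 0.6541, 0.9711),
    `Standard RBF (20)`         = c(0.5646, 0.3628, 0.7311, 0.9993),
    `Standard RBF (21)`         = c(0.6482, 0.3932, 0.6903, 0.9521),
    `Standard RBF (22)`         = c(0.5344, 0.3579, 0.7525, 0.9265),
    IDW                         = c(0.6447, 0.4442, 0.6077, 0.9993),
    Kriging                     = c(0.3800, 0.3376, 0.9175, 0.9650),
    check.names = FALSE)
  rownames(tab) <- c("RMSE", "MAE", "R", "D")
  structure(tab, hidden_units = c(21, 21, 10, 15, 20, 21, 22, NA, NA),
            class = c("comparison_table", "data.frame"))
}

#' Summary arithmetic over a comparison table
#'
#' Computes the mean testing RMSE of the standard-RBF trial columns and the
#' relative reduction achieved by the hybrid model's testing RMSE:
#' `100 * (mean_std_rbf - hybrid) / mean_std_rbf` (percent).
#'
#' @param tab a `comparison_table`.
#' @return list with `std_rbf_mean_rmse`, `hybrid_test_rmse`,
#'   `rmse_reduction_pct`.
#' @export
comparison_summary <- function(tab) {
  std_cols <- grep("^Standard RBF", colnames(tab))
  if (length(std_cols) == 0L) stop("no standard-RBF columns in the table")
  hy_col <- which(colnames(tab) == "SC-K-means-RBF (testing)")
  if (length(hy_col) != 1L) stop("no hybrid testing column in the table")
  mean_std <- mean(as.numeric(tab["RMSE", std_cols]))
  hy <- as.numeric(tab["RMSE", hy_col])
  list(std_rbf_mean_rmse = mean_std, hybrid_test_rmse = hy,
       rmse_reduction_pct = 100 * (mean_std - hy) / mean_std)
}

#' Write a comparison table as CSV
#'
#' One metric per row, one model per column; a `Hidden units` header row
#' carries each RBF column's unit count.
#'
#' @param tab a `comparison_table`.
#' @param path output file.
#' @export
write_comparison <- function(tab, path) {
  units <- attr(tab, "hidden_units")
  out <- rbind(`Hidden units` = ifelse(is.na(units), "-", units),
               format(as.matrix(tab), digits = 4))
  utils::write.csv(cbind(Metric = rownames(out), out), path,
                   row.names = FALSE)
  invisible(path)
}

#' Reproduce the field-study headline metrics from a sample file
#'
#' Loads the 61-sample field table, applies the positional 51/10 split,
#' fits the hybrid model with the radius calibrated to 21 hidden units, and
#' compares each testing statistic with the published reference within a
#' tolerance. The published values depend on unprinted preprocessing
#' choices, so each statistic carries its own pass flag rather than a
#' single verdict.
#'
#' @param path CSV/XLSX with the Time, X, Y, Z, DO schema (61 rows).
#' @param n_train leading rows used for fitting (default 51).
#' @param target_k calibrated hidden-unit count (default 21).
#' @param tol absolute tolerance per statistic (default 0.05).
#' @return data.frame with one row per statistic: value, reference,
#'   absolute difference, pass.
#' @export
reproduce_field_metrics <- function(path, n_train = 51L, target_k = 21L,
                                    tol = 0.05) {
  samples <- read_samples(path)
  sp <- split_train_test(samples, n_train)
  fit <- sc_kmeans_rbf(sp$train, target_k = target_k)
  m <- evaluate_model(fit, sp$test)
  ref <- reference_error_stats()[, "SC-K-means-RBF (testing)"]
  got <- c(m$rmse, m$mae, m$r, m$d)
  data.frame(metric = c("RMSE", "MAE", "R", "D"), value = got,
             reference = ref, abs_diff = abs(got - ref),
             pass = abs(got - ref) <= tol)
}
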