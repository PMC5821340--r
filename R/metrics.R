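# The four evaluation statistics: RMSE, MAE, Pearson R, Willmott index of
# agreement D.

.check_series <- function(obs, pred) {
  if (length(obs) != length(pred))
    stop("obs and pred must have equal length")
  if (length(obs) < 1L) stop("need at least one value")
  if (any(!is.finite(obs)) || any(!is.finite(pred)))
    stop("obs and pred must be finite")
}

#' Root mean square error
#' @param obs observed values.
#' @param pred predicted values.
#' @return RMSE (same units as the series, here mg/L).
#' @export
rmse <- function(obs, pred) {
  .check_series(obs, pred)
  sqrt(mean((pred - obs)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return MAE (mg/L).
#' @export
mae <- function(obs, pred) {
  .check_series(obs, pred)
  mean(abs(pred - obs))
}

#' Pearson correlation coefficient
#'
#' Computed from the product-moment form; `NaN` with a warning when either
#' series has zero variance (the coefficient is then undefined).
#'
#' @inheritParams rmse
#' @return R in \[-1, 1\], or `NaN` for degenerate input.
#' @export
pearson_r <- function(obs, pred) {
  .check_series(obs, pred)
  if (length(obs) < 2L) {
    warning("Pearson R undefined for a single observation")
    return(NaN)
  }
  do_ <- obs - mean(obs)
  dp <- pred - mean(pred)
  den <- sqrt(sum(do_^2) * sum(dp^2))
  if (den == 0) {
    warning("Pearson R undefined: a series has zero variance")
    return(NaN)
  }
  r <- sum(do_ * dp) / den
  min(1, max(-1, r))
}

#' Willmott index of agreement
#'
#' `D = 1 - sum((obs - pred)^2) / sum((|obs - m| + |pred - m|)^2)` with `m`
#' the observed mean. Equals 1 exactly when predictions match observations;
#' unbounded below.
#'
#' @inheritParams rmse
#' @return D <= 1, or `NaN` when the denominator is zero (both series
#'   constant and equal to the observed mean).
#' @export
willmott_d <- function(obs, pred) {
  .check_series(obs, pred)
  m <- mean(obs)
  den <- sum((abs(obs - m) + abs(pred - m))^2)
  if (den == 0) {
    warning("Willmott D undefined: all values identical in both series")
    return(NaN)
  }
  1 - sum((obs - pred)^2) / den
}

#' Full metrics report for one model on one sample set
#'
#' @inheritParams rmse
#' @return A `metrics_report`: list with `rmse`, `mae`, `r`, `d`, `n`.
#' @export
metrics_report <- function(obs, pred) {
  structure(list(rmse = rmse(obs, pred), mae = mae(obs, pred),
                 r = pearson_r(obs, pred), d = willmott_d(obs, pred),
                 n = length(obs)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4f  MAE = %.4f  R = %.4f  D = %.4f\n",
              x$n, x$rmse, x$mae, x$r, x$d))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(rmse = x$rmse, mae = x$mae, r = x$r, d = x$d, n = x$n)
}
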