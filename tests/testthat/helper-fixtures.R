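# Fixtures built in code at test time.

# two tight groups of 5 points each in 4-D, separation >> spread
two_group_points <- function(sep = 5, spread = 0.02, seed = 42L) {
  set.seed(seed)
  base <- rbind(matrix(rep(0, 4), 5, 4, byrow = TRUE),
                matrix(rep(sep, 4), 5, 4, byrow = TRUE))
  base + matrix(stats::rnorm(40, 0, spread), 10, 4)
}

# two-group sample set with DO levels 2 and 4 (for pipeline fits)
two_group_samples <- function(seed = 42L) {
  p <- two_group_points(seed = seed)
  sample_set(data.frame(t = p[, 1], x = abs(p[, 2]), y = abs(p[, 3]),
                        z = abs(p[, 4]), do = rep(c(2, 4), each = 5)),
             provenance = "fixture/two-group")
}

# a small Table-3-style CSV on disk; returns its path
write_sample_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("Time,X (m),Y (m),Z (m),Dissolved oxygen (mg/L)", rows), path)
  path
}

random_points <- function(m, d = 4L, seed) {
  set.seed(seed)
  matrix(stats::runif(m * d), m, d)
}

# an interpolator with a known analytic field, for grid/iso tests
analytic_model <- function(fun) {
  structure(list(fun = fun), class = "analytic_do_model")
}
predict.analytic_do_model <- function(object, newdata, ...) {
  q <- pondrbf::as_feature_matrix(newdata)
  object$fun(q[, "t"], q[, "x"], q[, "y"], q[, "z"])
}
registerS3method("predict", "analytic_do_model", predict.analytic_do_model)
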