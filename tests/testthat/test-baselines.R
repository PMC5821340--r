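test_that("IDW is exact at samples, symmetric between equals, and bounded", {
  s <- two_group_samples()
  m <- idw_fit(s)
  expect_equal(predict(m, s), s$do, tolerance = 1e-12)
  # midpoint of two samples with DO 2 and 4 -> 3
  df <- data.frame(t = c(0, 0), x = c(0, 10), y = c(0, 0), z = c(0, 0),
                   do = c(2, 4))
  m2 <- idw_fit(sample_set(df), normalize = FALSE)
  expect_equal(predict(m2, c(0, 5, 0, 0)), 3)
  # bounded by the observed range everywhere
  set.seed(2)
  q <- cbind(runif(50, 0, 40), runif(50, 0, 130), runif(50, 0, 45),
             runif(50, 0, 1.8))
  p <- predict(m, q)
  expect_true(all(p >= min(s$do) - 1e-12 & p <= max(s$do) + 1e-12))
})

test_that("IDW matches a hand-computed 3-point weighted mean", {
  df <- data.frame(t = 0, x = c(0, 4, 0), y = c(0, 0, 3), z = 0,
                   do = c(1, 2, 4))
  m <- idw_fit(sample_set(df), power = 2, normalize = FALSE)
  # query (0, 2, 0, 0): d = (2, 2, sqrt(13)); weights d^-2
  w <- c(1 / 4, 1 / 4, 1 / 13)
  expect_equal(predict(m, c(0, 2, 0, 0)), sum(w * c(1, 2, 4)) / sum(w),
               tolerance = 1e-12)
})

test_that("standard RBF baseline: exact limit, group recovery, determinism", {
  s <- two_group_samples()
  full <- standard_rbf_fit(s, k = nrow(s), seed = 3)
  expect_lt(rmse(s$do, predict(full, s)), 1e-6)
  two <- standard_rbf_fit(s, k = 2, seed = 11)
  pts <- normalize_features(two$normalizer, s)
  means <- rbind(colMeans(pts[1:5, ]), colMeans(pts[6:10, ]))
  expect_equal(two$centers[order(two$centers[, 1]), ],
               means[order(means[, 1]), ], tolerance = 1e-6,
               ignore_attr = TRUE)
  again <- standard_rbf_fit(s, k = 2, seed = 11)
  expect_identical(two$weights, again$weights)
  expect_error(standard_rbf_fit(s, k = 11), "k must")
})

test_that("empirical variogram averages binned semivariances", {
  # 1-D layout with known pair distances
  df <- data.frame(t = 0, x = c(0, 1, 2), y = 0, z = 0, do = c(0, 1, 3))
  emp <- empirical_variogram(as.matrix(df[, c("x", "y", "z")]), df$do,
                             lag = 1, n_lags = 5)
  # bin (0,1]: pairs (0,1),(1,2): mean(0.5*1, 0.5*4) = 1.25
  # bin (1,2]: pair (0,2): 0.5*9 = 4.5
  expect_equal(emp$gamma, c(1.25, 4.5))
  expect_equal(emp$npairs, c(2L, 1L))
})

test_that("spherical variogram model is valid, monotone and saturates", {
  expect_equal(spherical_gamma(0, 0.1, 0.3, 20), 0)
  h <- seq(0.1, 50, by = 0.1)
  g <- spherical_gamma(h, 0.1, 0.3, 20)
  expect_true(all(diff(g) >= -1e-12))
  expect_equal(spherical_gamma(c(20, 35), 0.1, 0.3, 20), c(0.4, 0.4))
  # fitted model on dense 1-D data is well-formed
  set.seed(9)
  df <- data.frame(t = 0, x = seq(0, 120, by = 4), y = 0, z = 0)
  df$do <- 2 + 0.3 * sin(df$x / 25) + rnorm(nrow(df), 0, 0.05)
  vm <- fit_variogram(sample_set(df), lag = 10, n_lags = 12)
  expect_true(vm$fitted)
  expect_gte(vm$sill, vm$nugget)
  expect_gt(vm$range, 0)
  # the pond is much smaller than 100 m x 20 lags: with too few occupied
  # bins the pragmatic fallback is used and flagged
  small <- sample_set(data.frame(t = 0, x = c(0, 5, 9, 13), y = 0, z = 0,
                                 do = c(2, 2.2, 1.9, 2.1)))
  vm2 <- fit_variogram(small, lag = 100, n_lags = 20)
  expect_false(vm2$fitted)
})

test_that("ordinary kriging interpolates exactly with zero nugget and its
           weights sum to one", {
  set.seed(14)
  df <- data.frame(t = 0, x = runif(12, 0, 100), y = runif(12, 0, 40),
                   z = runif(12, 0, 1.6), do = runif(12, 1.5, 2.5))
  s <- sample_set(df)
  vgm <- structure(list(nugget = 0, sill = 0.3, range = 60, fitted = TRUE,
                        lag = 100, n_lags = 20L),
                   class = "variogram_model")
  km <- kriging_fit(s, vgm = vgm)
  expect_equal(predict(km, s), s$do, tolerance = 1e-8)
  for (q in list(c(10, 10, 0.5), c(55, 20, 1.0), c(90, 35, 1.5))) {
    lam <- kriging_weights(km, q)
    expect_equal(sum(lam), 1, tolerance = 1e-10)
  }
})

test_that("kriging predictions match an independent direct solve", {
  df <- data.frame(t = 0, x = c(0, 10, 20, 30, 40), y = 0, z = 0,
                   do = c(2.0, 2.3, 1.8, 2.1, 1.6))
  s <- sample_set(df)
  vgm <- structure(list(nugget = 0.01, sill = 0.25, range = 25,
                        fitted = TRUE, lag = 100, n_lags = 20L),
                   class = "variogram_model")
  km <- kriging_fit(s, vgm = vgm)
  gamma_fun <- function(h) spherical_gamma(h, 0.01, 0.24, 25)
  coords <- as.matrix(df[, c("x", "y", "z")])
  for (qx in c(5, 12.5, 33)) {
    want <- oracle_kriging(coords, df$do, c(qx, 0, 0), gamma_fun)
    expect_equal(predict(km, c(0, qx, 0, 0)), want, tolerance = 1e-10)
  }
})

test_that("duplicate sample coordinates are averaged with a warning", {
  df <- data.frame(t = 0, x = c(0, 0, 10, 20), y = 0, z = 0,
                   do = c(2, 2.4, 1.8, 2.1))
  vgm <- structure(list(nugget = 0, sill = 0.2, range = 15, fitted = TRUE,
                        lag = 100, n_lags = 20L),
                   class = "variogram_model")
  expect_warning(km <- kriging_fit(sample_set(df), vgm = vgm), "duplicate")
  expect_equal(predict(km, c(0, 0, 0, 0)), 2.2, tolerance = 1e-8)
})

test_that("comparison table has the published layout and summary arithmetic", {
  spec <- field_spec()
  s <- sample_sensors(spec, "random", n = 61, seed = 12)
  sp <- split_train_test(s, 51)
  tab <- compare_models(sp$train, sp$test, rbf_k = c(5, 8), seed = 2,
                        lag = 20, n_lags = 10)
  expect_equal(dim(tab), c(4L, 6L))
  expect_equal(rownames(tab), c("RMSE", "MAE", "R", "D"))
  expect_true(all(c("SC-K-means-RBF (training)", "SC-K-means-RBF (testing)",
                    "IDW", "Kriging") %in% colnames(tab)))
  su <- comparison_summary(tab)
  expect_equal(su$std_rbf_mean_rmse,
               mean(as.numeric(tab["RMSE", c("Standard RBF (5)",
                                             "Standard RBF (8)")])))
  path <- tempfile(fileext = ".csv")
  write_comparison(tab, path)
  expect_equal(nrow(utils::read.csv(path)), 5L)  # hidden-units row + 4 metrics
})
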