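test_that("shared width follows d_max / sqrt(2n)", {
  c2 <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(rbf_width(c2), 0.5)           # 1 / sqrt(4)
  # 8 centers with max distance 4 -> width 1
  c8 <- matrix(0, 8, 4)
  c8[, 1] <- seq(0, 4, length.out = 8)
  expect_equal(rbf_width(c8), 1)             # 4 / sqrt(16)
  expect_error(rbf_width(matrix(1, 3, 4)), "degenerate")
  expect_error(rbf_width(matrix(1, 1, 4)), "degenerate")
})

test_that("design-matrix entries follow the Gaussian form", {
  ctr <- matrix(c(0, 0, 0, 0), 1)
  expect_equal(rbf_design(ctr, ctr, 0.7)[1, 1], 1)
  sig <- 0.33
  p <- matrix(c(sig * sqrt(2), 0, 0, 0), 1)
  expect_equal(rbf_design(p, ctr, sig)[1, 1], exp(-1), tolerance = 1e-12)
  far <- matrix(c(1e4, 0, 0, 0), 1)
  expect_equal(rbf_design(far, ctr, sig)[1, 1], 0)
  Phi <- rbf_design(random_points(20, seed = 1), random_points(5, seed = 2),
                    0.4)
  expect_true(all(Phi > 0 & Phi <= 1))
  expect_error(rbf_design(p, ctr, 0), "sigma")
})

test_that("weights solve the least-squares problem (normal-equations oracle)", {
  set.seed(5)
  p <- random_points(30, seed = 5)
  ctr <- random_points(6, seed = 6)
  Phi <- rbf_design(p, ctr, 0.5)
  y <- rnorm(30)
  w <- rbf_weights(Phi, y)
  w_oracle <- solve(t(Phi) %*% Phi, t(Phi) %*% y)
  expect_equal(w, drop(w_oracle), tolerance = 1e-8, ignore_attr = TRUE)
  # identity design returns y itself
  expect_equal(rbf_weights(diag(4), c(1, 2, 3, 4)), c(1, 2, 3, 4))
  # ridge shrinks toward zero relative to the unpenalized solution
  w_r <- rbf_weights(Phi, y, ridge = 10)
  expect_true(sum(w_r^2) < sum(w^2))
})

test_that("exact-interpolation limit: centers at the training points", {
  for (seed in c(3, 13)) {
    p <- random_points(25, seed = seed)
    y <- 2 + rnorm(25, 0, 0.2)
    sig <- rbf_width(p)
    Phi <- rbf_design(p, p, sig)
    w <- rbf_weights(Phi, y)
    expect_lt(sqrt(mean((Phi %*% w - y)^2)), 1e-6)
  }
})

test_that("prediction is linear in the weights and honors the normalizer", {
  s <- two_group_samples()
  nm <- fit_normalizer(s)
  ctr <- normalize_features(nm, s)[c(1, 6), , drop = FALSE]
  m1 <- rbf_model(ctr, 0.5, c(1, 0), nm)
  m2 <- rbf_model(ctr, 0.5, c(0, 2), nm)
  m12 <- rbf_model(ctr, 0.5, c(1, 2), nm)
  q <- as_feature_matrix(s)[c(2, 9), , drop = FALSE]
  expect_equal(predict(m12, q), predict(m1, q) + predict(m2, q),
               tolerance = 1e-12)
  # unit weight at a center predicts ~1 at that center's raw location
  raw_center <- denormalize_features(nm, ctr)[1, ]
  expect_equal(predict(m1, raw_center), 1, tolerance = 1e-9)
  expect_error(predict(m1, c(1, 2, NA, 0)), "finite")
})

test_that("prediction varies continuously with the query", {
  s <- two_group_samples()
  fit <- sc_kmeans_rbf(s)
  q <- c(0.1, 1, 1, 0.5)
  base <- predict(fit, q)
  eps <- 1e-6
  for (j in 1:4) {
    dq <- q
    dq[j] <- dq[j] + eps
    expect_lt(abs(predict(fit, dq) - base), 1e-3)
  }
})

test_that("model files round-trip bit-exactly and deterministically", {
  fit <- sc_kmeans_rbf(two_group_samples())
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_rbf_model(fit$model, f1)
  write_rbf_model(fit$model, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  m2 <- read_rbf_model(f1)
  expect_identical(unname(m2$centers), unname(fit$model$centers))
  expect_identical(m2$sigma, fit$model$sigma)
  expect_identical(m2$weights, fit$model$weights)
  expect_identical(m2$normalizer$offset, fit$model$normalizer$offset)
  q <- c(0.2, 2, 2, 0.3)
  expect_identical(predict(m2, q), predict(fit$model, q))
})
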