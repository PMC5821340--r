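test_that("clock times become minutes since the earliest sample", {
  path <- write_sample_csv(c("7:07,15,25,0.4,2.22",
                             "7:07,15,25,1,1.95",
                             "7:10,22.5,25,0.4,2.26"))
  s <- read_samples(path)
  expect_equal(s$t, c(0, 0, 3))
  expect_equal(s$x, c(15, 15, 22.5))
  expect_equal(s$do, c(2.22, 1.95, 2.26))
  # numeric times are taken as minutes as-is (keeps round-trips exact)
  path2 <- write_sample_csv(c("12,0,0,0.2,2.0", "15,1,1,0.4,2.1"))
  expect_equal(read_samples(path2)$t, c(12, 15))
})

test_that("schema and content errors are reported by name and row", {
  no_z <- tempfile(fileext = ".csv")
  writeLines(c("Time,X (m),Y (m),Dissolved oxygen (mg/L)", "7:07,1,2,2.2"),
             no_z)
  expect_error(read_samples(no_z), "Z \\(m\\)")
  bad <- write_sample_csv(c("7:07,1,2,0.4,2.2", "7:08,1,oops,0.4,2.3"))
  expect_error(read_samples(bad), "row 2")
  header_only <- write_sample_csv(character(0))
  expect_error(read_samples(header_only), "empty")
})

test_that("sample tables round-trip through write/read", {
  s <- two_group_samples()
  path <- tempfile(fileext = ".csv")
  write_samples(s, path)
  s2 <- read_samples(path)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("meteorological reader parses the standard schema and validates", {
  hdr <- paste("Time,Rainfall(mm),Wind speed(m/s),Wind direction(deg),",
               "Solar radiation(W/m2),Air temperature(C),",
               "Relative humidity(%),Atmos. Pressure(kPa)", sep = "")
  path <- tempfile(fileext = ".csv")
  writeLines(c(hdr,
               "2015-07-06 07:10:06,0.0,1.94,263.76,81.32,19.93,88.05,100.96",
               "2015-07-06 07:20:08,0.0,1.9,260.12,95.67,20.01,88.44,100.96"),
             path)
  m <- read_meteo(path)
  expect_equal(m$wind_speed[2], 1.9)
  expect_equal(m$wind_direction[2], 260.12)
  expect_equal(m$air_temperature[2], 20.01)
  empty <- tempfile(fileext = ".csv")
  writeLines(hdr, empty)
  expect_error(read_meteo(empty), "empty")
  bad <- tempfile(fileext = ".csv")
  writeLines(c(hdr,
               "2015-07-06 07:10:06,0.0,1.94,263.76,81.32,19.93,105,100.96"),
             bad)
  expect_error(read_meteo(bad), "relative_humidity")
})

test_that("the split is positional and preserves the multiset of rows", {
  s <- two_group_samples()
  sp <- split_train_test(s, 7)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_equal(rbind(as.data.frame(sp$train), as.data.frame(sp$test)),
               as.data.frame(s), ignore_attr = TRUE)
  expect_error(split_train_test(s, 10), "n_train")
  expect_error(split_train_test(s, 0), "n_train")
  two <- sample_set(as.data.frame(s)[1:2, ])
  sp2 <- split_train_test(two, 1)
  expect_equal(c(nrow(sp2$train), nrow(sp2$test)), c(1L, 1L))
})

test_that("min-max normalization maps features to [0,1] and inverts exactly", {
  df <- data.frame(t = c(0, 10, 40), x = c(0, 65, 130), y = c(5, 20, 44),
                   z = c(0.4, 1.0, 1.6), do = c(2, 2, 2))
  s <- sample_set(df)
  nm <- fit_normalizer(s)
  n <- normalize_features(nm, s)
  expect_equal(unname(n[, "z"]), c(0, 0.5, 1))  # hand min-max on the depths
  expect_true(all(n >= 0 & n <= 1))
  back <- denormalize_features(nm, n)
  expect_equal(unname(back), unname(as_feature_matrix(s)), tolerance = 1e-12)
})

test_that("a constant feature is flagged degenerate, not fatal", {
  df <- data.frame(t = c(5, 5, 5), x = c(0, 1, 2), y = c(0, 1, 2),
                   z = c(0, 1, 2), do = 1:3)
  nm <- fit_normalizer(sample_set(df))
  expect_true(nm$degenerate[["t"]])
  expect_equal(nm$scale[["t"]], 1)
  n <- normalize_features(nm, sample_set(df))
  expect_equal(unname(n[, "t"]), c(0, 0, 0))
})

test_that("normalizer round-trip holds on random finite input", {
  set.seed(1)
  df <- data.frame(t = runif(30, 0, 60), x = runif(30, 0, 130),
                   y = runif(30, 0, 45), z = runif(30, 0, 1.8),
                   do = runif(30, 1, 3))
  s <- sample_set(df)
  nm <- fit_normalizer(s)
  q <- matrix(runif(40, -50, 200), 10, 4)
  expect_equal(unname(denormalize_features(nm, normalize_features(nm, q))),
               q, tolerance = 1e-12)
})
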