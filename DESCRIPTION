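Package: pondrbf
Title: Hybrid Subtractive-Clustering K-Means RBF Interpolation of Dissolved
    Oxygen in Aquaculture Ponds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional spatio-temporal interpolation of dissolved
    oxygen (DO) fields in aquaculture ponds with a Gaussian radial basis
    function (RBF) network whose hidden layer is selected by subtractive
    clustering and refined by K-means ("SC-K-means-RBF").  Includes the
    comparison interpolators (standard RBF with trial hidden-unit counts,
    inverse distance weighting, ordinary Kriging with a spherical
    variogram), the four evaluation statistics (RMSE, MAE, Pearson R,
    Willmott index of agreement), dense 3-D pond-grid prediction products
    (horizontal DO slices, iso-concentration depth surfaces), and a
    synthetic-pond generator so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
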