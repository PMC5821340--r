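# Sample tables, train/test split and feature normalization.
#
# A sample set is a data.frame with columns t, x, y, z, do:
#   t  minutes since the start of the sampling window
#   x  meters along the pond length, y meters along the width
#   z  depth in meters, positive downward
#   do dissolved oxygen in mg/L

FEATURES <- c("t", "x", "y", "z")

#' Construct a sample set
#'
#' Validates and classes a data.frame of pond observations. Row order is
#' significant throughout the package: the train/test split is positional.
#'
#' @param df data.frame with numeric columns `t`, `x`, `y`, `z`, `do`.
#' @param provenance free-text tag recording where the rows came from.
#' @return A `sample_set` (a classed data.frame).
#' @export
sample_set <- function(df, provenance = "unknown") {
  need <- c(FEATURES, "do")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("sample set is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (nrow(df) < 1L) stop("empty sample set: need at least one observation")
  for (nm in need) {
    v <- df[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("column '", nm, "' must be finite numeric")
  }
  if (any(df$do < 0)) stop("dissolved oxygen must be >= 0 mg/L")
  if (any(df$z < 0)) stop("depth z must be >= 0 m (positive downward)")
  structure(df, provenance = provenance,
            class = c("sample_set", "data.frame"))
}

# canonical form of a header cell: lower case, unit decorations stripped
.canon_header <- function(h) {
  h <- tolower(trimws(h))
  gsub("[^a-z]", "", h)
}

.sample_header_map <- c(
  time = "t", t = "t",
  x = "x", xm = "x",
  y = "y", ym = "y",
  z = "z", zm = "z", depth = "z", depthm = "z",
  dissolvedoxygen = "do", dissolvedoxygenmgl = "do", do = "do", domgl = "do"
)

# "7:07" / "07:07:30" -> minutes; plain numbers pass through
.parse_time_minutes <- function(s) {
  s <- trimws(as.character(s))
  out <- suppressWarnings(as.numeric(s))
  clock <- grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", s)
  if (any(clock)) {
    parts <- strsplit(s[clock], ":", fixed = TRUE)
    out[clock] <- vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] * 60 + p[2] + if (length(p) == 3L) p[3] / 60 else 0
    }, numeric(1))
  }
  bad <- !clock & is.na(out) & nzchar(s)
  if (any(bad))
    stop("cannot parse time value(s): ", paste(unique(s[bad]), collapse = ", "))
  out
}

#' Read a sample table
#'
#' Reads CSV (or XLSX, first worksheet, if \pkg{readxl} is installed) with
#' the columns Time, X (m), Y (m), Z (m), Dissolved oxygen (mg/L); header
#' matching is case-insensitive and tolerant of unit suffixes. Clock times
#' ("H:MM") are converted to minutes elapsed since the earliest time in the
#' file; numeric times are taken as minutes as-is.
#'
#' @param path file to read.
#' @param dialect `"auto"` (by extension), `"csv"` or `"xlsx"`.
#' @return A [sample_set()] in file order.
#' @export
read_samples <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  raw <- .read_table_raw(path, dialect)
  if (nrow(raw) < 1L) stop("empty input: '", path, "' has a header but no data rows")
  canon <- .canon_header(names(raw))
  mapped <- .sample_header_map[canon]
  for (want in c(FEATURES, "do")) {
    if (!want %in% mapped)
      stop("schema error in '", path, "': no column matching '",
           c(t = "Time", x = "X (m)", y = "Y (m)", z = "Z (m)",
             do = "Dissolved oxygen (mg/L)")[want], "'")
  }
  names(raw) <- ifelse(is.na(mapped), names(raw), mapped)
  t_raw <- trimws(as.character(raw[["t"]]))
  t_min <- .parse_time_minutes(t_raw)
  # clock-format files are re-anchored at the earliest time; numeric
  # minutes pass through untouched so written tables round-trip
  if (any(grepl(":", t_raw, fixed = TRUE))) t_min <- t_min - min(t_min)
  num <- lapply(c("x", "y", "z", "do"), function(nm) {
    v <- suppressWarnings(as.numeric(as.character(raw[[nm]])))
    if (any(is.na(v)))
      stop("parse error in '", path, "', column '", nm, "', row ",
           which(is.na(v))[1], ": non-numeric cell")
    v
  })
  df <- data.frame(t = t_min, x = num[[1]], y = num[[2]],
                   z = num[[3]], do = num[[4]])
  sample_set(df, provenance = path)
}

.read_table_raw <- function(path, dialect) {
  if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("xlsx input needs the 'readxl' package; convert to CSV instead")
    as.data.frame(readxl::read_excel(path, sheet = 1, col_types = "text"))
  } else {
    utils::read.csv(path, check.names = FALSE, colClasses = "character",
                    strip.white = TRUE)
  }
}

#' Write a sample table
#'
#' CSV with the canonical header; numeric content round-trips through
#' [read_samples()].
#'
#' @param x a [sample_set()].
#' @param path output file.
#' @export
write_samples <- function(x, path) {
  out <- data.frame(Time = x$t, `X (m)` = x$x, `Y (m)` = x$y, `Z (m)` = x$z,
                    `Dissolved oxygen (mg/L)` = x$do, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.meteo_header_map <- c(
  time = "timestamp", timestamp = "timestamp",
  rainfall = "rainfall", rainfallmm = "rainfall",
  windspeed = "wind_speed", windspeedms = "wind_speed",
  winddirection = "wind_direction",
  solarradiation = "solar_radiation", solarradiationwm = "solar_radiation",
  airtemperature = "air_temperature", airtemperaturec = "air_temperature",
  relativehumidity = "relative_humidity",
  atmospressure = "atmos_pressure", atmospressurekpa = "atmos_pressure",
  atmosphericpressure = "atmos_pressure"
)

#' Read a meteorological table
#'
#' CSV with columns Time, Rainfall(mm), Wind speed(m/s), Wind direction(deg),
#' Solar radiation(W/m2), Air temperature(degC), Relative humidity(%),
#' Atmos. Pressure(kPa). Wind direction must lie in \[0, 360) and relative
#' humidity in \[0, 100\].
#'
#' @param path file to read.
#' @return data.frame of records in file order, timestamps parsed as POSIXct.
#' @export
read_meteo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (nrow(raw) < 1L) stop("empty input: '", path, "' has no data rows")
  canon <- .canon_header(names(raw))
  # unit strings vary; match on the alphabetic stem
  stem <- sub("(mm|ms|wm|deg|degc|c|kpa)$", "", canon)
  mapped <- .meteo_header_map[canon]
  mapped[is.na(mapped)] <- .meteo_header_map[stem][is.na(mapped)]
  need <- c("timestamp", "rainfall", "wind_speed", "wind_direction",
            "solar_radiation", "air_temperature", "relative_humidity",
            "atmos_pressure")
  for (want in need)
    if (!want %in% mapped)
      stop("schema error in '", path, "': no column matching '", want, "'")
  names(raw) <- ifelse(is.na(mapped), names(raw), mapped)
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                  "%Y/%m/%d %H:%M:%S"))
  num <- lapply(setdiff(need, "timestamp"), function(nm) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    if (any(is.na(v)))
      stop("parse error in '", path, "', column '", nm, "', row ",
           which(is.na(v))[1])
    v
  })
  df <- data.frame(timestamp = ts)
  df[setdiff(need, "timestamp")] <- num
  if (any(df$wind_direction < 0 | df$wind_direction >= 360))
    stop("validation error: wind_direction outside [0, 360)")
  if (any(df$relative_humidity < 0 | df$relative_humidity > 100))
    stop("validation error: relative_humidity outside [0, 100]")
  df
}

#' Positional train/test split
#'
#' The first `n_train` rows (file order) become the training set, the rest
#' the testing set. Never randomized: the field protocol fixes the split.
#'
#' @param data a [sample_set()].
#' @param n_train number of leading rows to train on; `1 <= n_train < nrow`.
#' @return list with elements `train` and `test`, both sample sets.
#' @export
split_train_test <- function(data, n_train) {
  n <- nrow(data)
  if (length(n_train) != 1L || n_train < 1L || n_train >= n)
    stop("n_train must satisfy 1 <= n_train < ", n)
  prov <- attr(data, "provenance")
  list(train = sample_set(data[seq_len(n_train), , drop = FALSE],
                          provenance = paste0(prov, "[train]")),
       test = sample_set(data[(n_train + 1L):n, , drop = FALSE],
                         provenance = paste0(prov, "[test]")))
}

#' Fit a min-max feature normalizer
#'
#' Maps each of (t, x, y, z) to \[0, 1\] by the training-set minimum and
#' range, making minutes and meters commensurable before any Euclidean
#' distance is computed. A feature with fewer than two distinct values
#' keeps scale 1 (offset at its value) and is flagged as degenerate.
#'
#' @param data a [sample_set()] or numeric matrix with columns t, x, y, z.
#' @return A `do_normalizer` with per-feature `offset`, `scale` and
#'   `degenerate` flags.
#' @export
fit_normalizer <- function(data) {
  m <- as_feature_matrix(data)
  offset <- apply(m, 2, min)
  rng <- apply(m, 2, max) - offset
  degenerate <- rng <= 0
  scale <- ifelse(degenerate, 1, rng)
  structure(list(offset = offset, scale = scale, degenerate = degenerate,
                 method = "min-max"),
            class = "do_normalizer")
}

#' Identity normalizer (raw units)
#'
#' Used by the `--no-normalize` path: distances are then computed over raw
#' (minutes, meters) coordinates.
#' @return A `do_normalizer` with offset 0 and scale 1 on every feature.
#' @export
identity_normalizer <- function() {
  z <- stats::setNames(rep(0, 4), FEATURES)
  structure(list(offset = z, scale = z + 1,
                 degenerate = stats::setNames(rep(FALSE, 4), FEATURES),
                 method = "identity"),
            class = "do_normalizer")
}

#' @export
print.do_normalizer <- function(x, ...) {
  cat("feature normalizer (", x$method, ")\n", sep = "")
  print(rbind(offset = x$offset, scale = x$scale))
  invisible(x)
}

#' Apply / invert a normalizer
#'
#' @param norm a `do_normalizer`.
#' @param data sample set or matrix with columns t, x, y, z.
#' @return matrix of normalized (resp. raw) feature rows.
#' @export
normalize_features <- function(norm, data) {
  m <- as_feature_matrix(data)
  sweep(sweep(m, 2, norm$offset, "-"), 2, norm$scale, "/")
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(norm, data) {
  m <- as_feature_matrix(data)
  sweep(sweep(m, 2, norm$scale, "*"), 2, norm$offset, "+")
}

#' Extract the (t, x, y, z) feature matrix from tabular input
#'
#' @param data sample set, data.frame with t/x/y/z columns, numeric matrix
#'   with four columns, or a length-4 numeric vector (one point).
#' @return numeric matrix with columns t, x, y, z.
#' @export
as_feature_matrix <- function(data) {
  if (is.matrix(data)) {
    if (ncol(data) != 4L) stop("feature matrix must have 4 columns (t,x,y,z)")
    colnames(data) <- FEATURES
    return(data)
  }
  if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != 4L) stop("a single query point must have 4 coordinates")
    return(matrix(data, 1L, dimnames = list(NULL, FEATURES)))
  }
  if (is.data.frame(data)) {
    miss <- setdiff(FEATURES, names(data))
    if (length(miss) > 0L)
      stop("missing feature column(s): ", paste(miss, collapse = ", "))
    return(as.matrix(data[, FEATURES]))
  }
  stop("cannot interpret input as (t, x, y, z) features")
}
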