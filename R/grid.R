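# Dense prediction products over the pond: horizontal DO slices and the
# iso-concentration depth surface.

#' Pond geometry
#'
#' @param length pond length in meters (x axis), default 130.
#' @param width pond width in meters (y axis), default 45.
#' @param max_depth maximum depth in meters, default 1.8.
#' @return A `pond_geometry` list.
#' @export
pond_geometry <- function(length = 130, width = 45, max_depth = 1.8) {
  if (length <= 0 || width <= 0 || max_depth <= 0)
    stop("pond dimensions must be positive")
  structure(list(length = length, width = width, max_depth = max_depth),
            class = "pond_geometry")
}

.field_grid <- function(x, y, values, fixed, kind) {
  stopifnot(nrow(values) == length(y), ncol(values) == length(x))
  structure(list(x = x, y = y, values = values, fixed = fixed, kind = kind),
            class = "field_grid")
}

#' Horizontal DO slice
#'
#' Predicts DO on a regular `nx` by `ny` grid over the pond rectangle at a
#' fixed time and depth. A pure function of the model: values at shared
#' nodes do not depend on the resolution.
#'
#' @param model fitted interpolator (anything [evaluate_model()] accepts).
#' @param t time in minutes since the window start.
#' @param z depth in meters (must lie inside the pond).
#' @param geom a [pond_geometry()].
#' @param nx,ny grid resolution (default 50 x 50).
#' @return A `field_grid`: axes `x`, `y`, an `ny x nx` DO matrix `values`
#'   (rows follow `y`), and the fixed coordinates.
#' @export
horizontal_slice <- function(model, t, z, geom = pond_geometry(),
                             nx = 50L, ny = 50L) {
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  if (z < 0 || z > geom$max_depth)
    stop("z = ", z, " lies outside the pond depth [0, ", geom$max_depth, "]")
  xs <- seq(0, geom$length, length.out = nx)
  ys <- seq(0, geom$width, length.out = ny)
  nodes <- cbind(t = t, x = rep(xs, times = ny), y = rep(ys, each = nx),
                 z = z)
  vals <- matrix(predict(model, nodes), nrow = ny, ncol = nx, byrow = TRUE)
  .field_grid(xs, ys, vals, fixed = list(t = t, z = z), kind = "slice")
}

#' Iso-concentration depth surface
#'
#' For every horizontal position, the shallowest depth at which predicted
#' DO crosses `threshold` going down: `nz` depth levels are scanned from
#' the surface and the bracketing pair is refined by linear interpolation.
#' Columns that never cross carry the sentinel `max_depth` and are flagged
#' in the `reached` matrix.
#'
#' @param model fitted interpolator.
#' @param t time in minutes.
#' @param threshold DO threshold in mg/L (> 0); 2 mg/L is the hypoxia
#'   warning level for crab ponds.
#' @param geom a [pond_geometry()].
#' @param nx,ny horizontal resolution.
#' @param nz number of scanned depth levels (>= 3, default 33).
#' @return A `field_grid` of depths (m) with attribute matrix `reached`.
#' @export
iso_depth_surface <- function(model, t, threshold, geom = pond_geometry(),
                              nx = 50L, ny = 50L, nz = 33L) {
  if (threshold <= 0) stop("threshold must be > 0 mg/L")
  if (nz < 3L) stop("nz must be >= 3")
  xs <- seq(0, geom$length, length.out = nx)
  ys <- seq(0, geom$width, length.out = ny)
  zs <- seq(0, geom$max_depth, length.out = nz)
  nodes <- cbind(t = t,
                 x = rep(xs, times = ny * nz),
                 y = rep(rep(ys, each = nx), times = nz),
                 z = rep(zs, each = nx * ny))
  v <- array(predict(model, nodes), dim = c(nx, ny, nz))
  depth <- matrix(geom$max_depth, nrow = ny, ncol = nx)
  reached <- matrix(FALSE, nrow = ny, ncol = nx)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    col <- v[ix, iy, ]
    below <- which(col <= threshold)
    if (length(below) == 0L) next
    k <- below[1]
    reached[iy, ix] <- TRUE
    depth[iy, ix] <- if (k == 1L) zs[1] else {
      zs[k - 1] + (col[k - 1] - threshold) / (col[k - 1] - col[k]) *
        (zs[k] - zs[k - 1])
    }
  }
  g <- .field_grid(xs, ys, depth, fixed = list(t = t, threshold = threshold),
                   kind = "iso")
  g$reached <- reached
  g
}

#' Export a prediction grid
#'
#' `csv-long` writes one row per node — `(t, x, y, z, do)` for slices,
#' `(t, x, y, depth, reached)` for iso surfaces — with the y axis as the
#' outer loop and x as the inner loop (row-major in (y, x)).
#' `ascii-matrix` writes commented axis headers followed by the value
#' matrix (one row per y). Both round-trip through [read_grid()].
#'
#' @param grid a `field_grid`.
#' @param path output file.
#' @param format `"csv-long"` or `"ascii-matrix"`.
#' @export
export_grid <- function(grid, path, format = c("csv-long", "ascii-matrix")) {
  format <- match.arg(format)
  nx <- length(grid$x); ny <- length(grid$y)
  if (format == "csv-long") {
    df <- data.frame(t = grid$fixed$t,
                     x = rep(grid$x, times = ny),
                     y = rep(grid$y, each = nx))
    if (grid$kind == "slice") {
      df$z <- grid$fixed$z
      df$do <- as.vector(t(grid$values))
    } else {
      df$depth <- as.vector(t(grid$values))
      df$reached <- as.vector(t(grid$reached))
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# kind: ", grid$kind),
                 paste0("# fixed: ", paste(names(grid$fixed), unlist(grid$fixed),
                                           sep = "=", collapse = " ")),
                 paste0("# x: ", paste(.num_out(grid$x), collapse = " ")),
                 paste0("# y: ", paste(.num_out(grid$y), collapse = " "))),
               con)
    utils::write.table(grid$values, con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Re-read an exported grid
#'
#' @param path file written by [export_grid()].
#' @param format the format it was written in.
#' @return A `field_grid`.
#' @export
read_grid <- function(path, format = c("csv-long", "ascii-matrix")) {
  format <- match.arg(format)
  if (format == "csv-long") {
    df <- utils::read.csv(path)
    xs <- unique(df$x); ys <- unique(df$y)
    kind <- if ("do" %in% names(df)) "slice" else "iso"
    vcol <- if (kind == "slice") df$do else df$depth
    vals <- matrix(vcol, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    fixed <- if (kind == "slice") list(t = df$t[1], z = df$z[1])
             else list(t = df$t[1])
    g <- .field_grid(xs, ys, vals, fixed, kind)
    if (kind == "iso")
      g$reached <- matrix(df$reached, nrow = length(ys), byrow = TRUE)
    g
  } else {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    kind <- sub("^# kind: ", "", hdr[1])
    xs <- as.numeric(strsplit(sub("^# x: ", "", hdr[3]), " ")[[1]])
    ys <- as.numeric(strsplit(sub("^# y: ", "", hdr[4]), " ")[[1]])
    vals <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)]))
    dimnames(vals) <- NULL
    fixed_txt <- strsplit(sub("^# fixed: ", "", hdr[2]), " ")[[1]]
    fixed <- lapply(strsplit(fixed_txt, "="), function(p) as.numeric(p[2]))
    names(fixed) <- vapply(strsplit(fixed_txt, "="), `[`, "", 1)
    .field_grid(xs, ys, vals, fixed, kind)
  }
}
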