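# Synthetic pond: a deterministic ground-truth DO field plus sensor-style
# noisy sampling, so every pipeline stage is testable without field data.
#
# The field emulates what the method assumes about a real crab pond: DO
# decreasing with depth, a horizontal gradient aligned with the wind
# (leeward side richer), optional local hotspots (aerator / uptake
# footprints), a slow diurnal drift, and additive sensor noise.

#' Specification of a synthetic DO field
#'
#' Defaults track the magnitudes of the 45 m x 130 m crab-pond campaign
#' this package models: DO near 2 mg/L at dawn, about -0.4 mg/L per meter
#' of depth, wind from 260 degrees, and a fraction of a mg/L of horizontal
#' contrast across the pond.
#'
#' @param geom a [pond_geometry()].
#' @param base_do DO at the pond center and surface at `t = 0` (mg/L).
#' @param depth_slope change of DO per meter of depth (mg/L/m, negative).
#' @param wind_direction compass azimuth the wind blows from (degrees,
#'   0 = north, 90 = east); the DO gradient points downwind.
#' @param wind_gradient DO change per meter along the downwind direction
#'   (mg/L/m).
#' @param hotspots data.frame with columns x, y, z (m), amplitude (mg/L)
#'   and radius (m); each adds `amplitude * exp(-d^2 / radius^2)`.
#' @param diurnal_slope DO drift per minute (mg/L/min; dawn DO rises
#'   slowly as photosynthesis starts).
#' @param noise_sd standard deviation of the additive Gaussian sensor
#'   noise (mg/L).
#' @return A `field_spec` list.
#' @export
field_spec <- function(geom = pond_geometry(), base_do = 2.0,
                       depth_slope = -0.4, wind_direction = 260,
                       wind_gradient = 0.0015,
                       hotspots = default_hotspots(),
                       diurnal_slope = 0.002, noise_sd = 0.05) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(hotspots) && nrow(hotspots) > 0 && any(hotspots$radius <= 0))
    stop("hotspot radius must be > 0")
  structure(list(geom = geom, base_do = base_do, depth_slope = depth_slope,
                 wind_direction = wind_direction %% 360,
                 wind_gradient = wind_gradient, hotspots = hotspots,
                 diurnal_slope = diurnal_slope, noise_sd = noise_sd),
            class = "field_spec")
}

#' Default hotspot pair
#'
#' One oxygen-rich patch (e.g. near an aerator) and one depleted patch
#' (e.g. a feeding/uptake zone), both a few tens of meters across.
#' @return data.frame of two hotspots.
#' @export
default_hotspots <- function() {
  data.frame(x = c(30, 100), y = c(12, 33), z = c(0.4, 0.8),
             amplitude = c(0.12, -0.12), radius = c(18, 20))
}

#' Compass azimuth of the planted DO gradient
#'
#' The DO gradient points downwind: wind from `wind_direction` pushes
#' oxygen-rich surface water toward `wind_direction + 180`.
#' @param spec a [field_spec()].
#' @return azimuth in degrees \[0, 360).
#' @export
planted_gradient_azimuth <- function(spec) {
  (spec$wind_direction + 180) %% 360
}

#' Noise-free ground-truth DO
#'
#' @param spec a [field_spec()].
#' @param t,x,y,z coordinates (vectors recycle); minutes and meters, with
#'   x east along the pond length and y north along the width.
#' @return DO in mg/L (deterministic, noise free).
#' @export
true_do <- function(spec, t, x, y, z) {
  g <- spec$geom
  if (any(x < 0 | x > g$length | y < 0 | y > g$width |
          z < 0 | z > g$max_depth))
    stop("point outside the pond")
  az <- planted_gradient_azimuth(spec) * pi / 180
  ux <- sin(az); uy <- cos(az)
  proj <- (x - g$length / 2) * ux + (y - g$width / 2) * uy
  v <- spec$base_do + spec$depth_slope * z + spec$wind_gradient * proj +
    spec$diurnal_slope * t
  hs <- spec$hotspots
  if (!is.null(hs) && nrow(hs) > 0) {
    for (i in seq_len(nrow(hs))) {
      d2 <- (x - hs$x[i])^2 + (y - hs$y[i])^2 + (z - hs$z[i])^2
      v <- v + hs$amplitude[i] * exp(-d2 / hs$radius[i]^2)
    }
  }
  v
}

#' Draw sensor-style samples from a synthetic field
#'
#' `layout = "fig4"` reproduces the field campaign's station plan: 9
#' stations on a regular 3 x 3 grid each profiled at depths 0.4 / 1.0 /
#' 1.6 m, plus 10 shallow stations at 0.2 m — 37 samples. `layout =
#' "random"` scatters `n` samples uniformly over the pond with depths
#' drawn from the instrument depths 0.2 / 0.4 / 1.0 / 1.6 m. Timestamps
#' are spread evenly across the sampling window in visit order.
#' Observed DO is `true_do + N(0, noise_sd)`, clipped at 0.
#'
#' @param spec a [field_spec()].
#' @param layout `"fig4"` or `"random"`.
#' @param n sample count for the random layout.
#' @param t_window sampling-window length in minutes (default 40, the time
#'   a handheld profile of the pond takes).
#' @param seed integer seed; the same seed reproduces the identical set.
#' @return A [sample_set()].
#' @export
sample_sensors <- function(spec, layout = c("fig4", "random"), n = 100L,
                           t_window = 40, seed = 1L) {
  layout <- match.arg(layout)
  g <- spec$geom
  if (layout == "fig4") {
    sx <- g$length * c(0.25, 0.5, 0.75)
    sy <- g$width * c(0.25, 0.5, 0.75)
    deep <- expand.grid(x = sx, y = sy)
    deep <- deep[rep(seq_len(nrow(deep)), each = 3L), ]
    deep$z <- rep(c(0.4, 1.0, 1.6), times = 9L)
    shallow <- data.frame(x = g$length * seq(0.1, 0.9, length.out = 5L),
                          y = rep(g$width * c(0.3, 0.7), each = 5L))
    shallow$z <- 0.2
    pts <- rbind(deep, shallow)
  } else {
    if (n < 1L) stop("n must be >= 1")
    set.seed(as.integer(seed) %% .Machine$integer.max)
    pts <- data.frame(x = stats::runif(n, 0, g$length),
                      y = stats::runif(n, 0, g$width),
                      z = sample(c(0.2, 0.4, 1.0, 1.6), n, replace = TRUE))
  }
  m <- nrow(pts)
  pts$t <- seq(0, t_window, length.out = m)
  set.seed((as.integer(seed) + 1L) %% .Machine$integer.max)
  clean <- true_do(spec, pts$t, pts$x, pts$y, pts$z)
  obs <- pmax(clean + stats::rnorm(m, 0, spec$noise_sd), 0)
  sample_set(data.frame(t = pts$t, x = pts$x, y = pts$y, z = pts$z,
                        do = obs),
             provenance = sprintf("synthetic/%s seed=%d", layout, seed))
}

#' Matching synthetic meteorological table
#'
#' A small Table-4-style record set carrying the planted wind direction,
#' for pipelines that read a paired meteorological file.
#'
#' @param spec a [field_spec()].
#' @param t_window window length in minutes.
#' @param step record spacing in minutes (default 10).
#' @param start origin timestamp.
#' @return data.frame in the meteorological schema.
#' @export
synthetic_meteo <- function(spec, t_window = 40, step = 10,
                            start = as.POSIXct("2015-07-06 07:00:00",
                                               tz = "UTC")) {
  tt <- seq(0, t_window, by = step)
  data.frame(timestamp = start + tt * 60, rainfall = 0,
             wind_speed = 1.9, wind_direction = spec$wind_direction,
             solar_radiation = 80 + 1.2 * tt, air_temperature = 20 + 0.01 * tt,
             relative_humidity = 88 - 0.05 * tt, atmos_pressure = 100.96)
}

#' Estimate the azimuth of a slice's horizontal gradient
#'
#' Fits a plane `do ~ x + y` to a horizontal slice and returns the compass
#' azimuth of the fitted gradient (direction of increasing DO); used to
#' check that a fitted model reproduces the planted wind alignment.
#'
#' @param grid a slice `field_grid` from [horizontal_slice()].
#' @return azimuth in degrees \[0, 360).
#' @export
slice_gradient_azimuth <- function(grid) {
  nx <- length(grid$x)
  df <- data.frame(v = as.vector(t(grid$values)),
                   x = rep(grid$x, times = length(grid$y)),
                   y = rep(grid$y, each = nx))
  co <- stats::coef(stats::lm(v ~ x + y, data = df))
  (atan2(co[["x"]], co[["y"]]) * 180 / pi) %% 360
}

#' Smallest absolute angular difference between two azimuths
#' @param a,b azimuths in degrees.
#' @return difference in \[0, 180\].
#' @export
angle_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
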