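#' Kilometres per degree of latitude
#'
#' Single geodetic constant used everywhere in the package: the length of one
#' degree of a great circle on a sphere of mean Earth radius 6371.0 km.
#' Zonal distances scale as `KM_PER_DEG * cos(lat)`.
#'
#' @format A length-one numeric, 111.195 km/degree.
#' @export
KM_PER_DEG <- 111.195

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Kilometres per degree of longitude at a given latitude
#' @param lat latitude in degrees north.
#' @return km per degree of longitude (shrinks as `cos(lat)`).
#' @export
km_per_deg_lon <- function(lat) KM_PER_DEG * cos(.deg2rad(lat))

.check_axis <- function(x, name) {
  if (length(x) < 2) stop(name, " axis needs at least 2 coordinates")
  d <- diff(x)
  if (any(d <= 0)) stop(name, " coordinates must be strictly increasing")
  if (max(d) - min(d) > 1e-9) stop(name, " spacing must be regular (within 1e-9 degrees)")
  invisible(mean(d))
}

#' Gridded scalar climate field
#'
#' Container for a scalar field (e.g. temperature in degC) on a regular
#' latitude-longitude grid, for one year or one averaging period.
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat latitudes (degrees north), strictly increasing, regular spacing.
#' @param lon longitudes (degrees east), strictly increasing, regular spacing.
#' @param period numeric length-2 half-open year window `[start, end)`, or a
#'   single year (treated as `[y, y+1)`).
#' @param units value units label, default `"degC"`.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, period = NULL, units = "degC") {
  values <- as.matrix(values)
  .check_axis(lat, "lat")
  .check_axis(lon, "lon")
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("values must be length(lat) x length(lon)")
  if (!all(is.finite(values))) stop("field values must be finite")
  if (!is.null(period)) {
    if (length(period) == 1) period <- c(period, period + 1)
    if (length(period) != 2 || period[2] <= period[1])
      stop("period must be a half-open window [start, end) with end > start")
  }
  structure(list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
                 period = period, units = units),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("gridded_field: %d x %d (lat x lon), %s\n",
              nrow(x$values), ncol(x$values), x$units))
  cat(sprintf("  lat %g..%g, lon %g..%g\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  if (!is.null(x$period))
    cat(sprintf("  period [%g, %g)\n", x$period[1], x$period[2]))
  cat(sprintf("  values %.3f..%.3f\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.gridded_field <- function(x, ...) {
  graphics::image(x$lon, x$lat, t(x$values), xlab = "lon (deg E)",
                  ylab = "lat (deg N)", ...)
  invisible(x)
}

#' Midpoint year of a field's averaging period
#' @param f a `gridded_field`.
#' @return numeric midpoint year.
#' @export
period_midpoint <- function(f) {
  if (is.null(f$period)) stop("field has no period label")
  mean(f$period)
}

.same_grid <- function(a, b) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) < 1e-9 && max(abs(a$lon - b$lon)) < 1e-9
}

#' Digital elevation model grid
#'
#' Signed elevation in metres on a regular lat-lon grid; depths (bathymetry)
#' are negative so one axis convention covers elevation and depth shifts.
#'
#' @param values elevation matrix in metres, `length(lat)` x `length(lon)`.
#' @param lat,lon regular axes in degrees as for [gridded_field()].
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(values, lat, lon) {
  f <- gridded_field(values, lat, lon, units = "m")
  structure(list(values = f$values, lat = f$lat, lon = f$lon, units = "m"),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("dem_grid: %d x %d (lat x lon), elevation %.1f..%.1f m\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# Bilinear interpolation on a regular lat/lon grid; error outside bounds.
.bilinear <- function(values, lat, lon, qlat, qlon) {
  if (any(qlat < lat[1] - 1e-12) || any(qlat > lat[length(lat)] + 1e-12) ||
      any(qlon < lon[1] - 1e-12) || any(qlon > lon[length(lon)] + 1e-12))
    stop("query point outside grid bounds")
  qlat <- pmin(pmax(qlat, lat[1]), lat[length(lat)])
  qlon <- pmin(pmax(qlon, lon[1]), lon[length(lon)])
  dlat <- (lat[length(lat)] - lat[1]) / (length(lat) - 1)
  dlon <- (lon[length(lon)] - lon[1]) / (length(lon) - 1)
  fi <- (qlat - lat[1]) / dlat
  fj <- (qlon - lon[1]) / dlon
  i0 <- pmin(pmax(floor(fi), 0), length(lat) - 2)
  j0 <- pmin(pmax(floor(fj), 0), length(lon) - 2)
  wi <- fi - i0
  wj <- fj - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L   # 1-based
  (1 - wi) * (1 - wj) * values[cbind(i0, j0)] +
    (1 - wi) * wj       * values[cbind(i0, j0 + 1L)] +
    wi * (1 - wj)       * values[cbind(i0 + 1L, j0)] +
    wi * wj             * values[cbind(i0 + 1L, j0 + 1L)]
}

#' Sample a DEM at a point
#'
#' Bilinear interpolation of the elevation surface; exact on linear slopes.
#'
#' @param dem a [dem_grid()].
#' @param lat,lon query coordinates in degrees (vectorized).
#' @return elevation(s) in metres (negative below sea level).
#' @export
sample_elevation <- function(dem, lat, lon) {
  stopifnot(inherits(dem, "dem_grid"))
  .bilinear(dem$values, dem$lat, dem$lon, lat, lon)
}
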