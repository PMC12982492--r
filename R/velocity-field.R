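#' Climate-velocity field
#'
#' Per-node horizontal displacement-rate vectors (km/yr) on a regular lat-lon
#' grid, produced by either estimator. Nodes flagged invalid (e.g. vanishing
#' spatial gradient under the gradient method) carry exactly zero velocity.
#'
#' @param v_east,v_north numeric matrices of velocity components in km/yr,
#'   `length(lat)` rows x `length(lon)` columns.
#' @param lat,lon regular axes in degrees as for [gridded_field()].
#' @param valid logical matrix of node validity (default all `TRUE`).
#' @param method `"gradient"` or `"match"`.
#' @param dt time interval in years between the two period midpoints.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(v_east, v_north, lat, lon, valid = NULL,
                           method = c("gradient", "match", "prescribed"),
                           dt = NA_real_) {
  method <- match.arg(method)
  v_east <- as.matrix(v_east); v_north <- as.matrix(v_north)
  .check_axis(lat, "lat"); .check_axis(lon, "lon")
  if (!all(dim(v_east) == c(length(lat), length(lon))) ||
      !all(dim(v_north) == c(length(lat), length(lon))))
    stop("component matrices must be length(lat) x length(lon)")
  if (is.null(valid)) valid <- matrix(TRUE, length(lat), length(lon))
  valid <- as.matrix(valid)
  if (!all(dim(valid) == dim(v_east))) stop("valid mask dimension mismatch")
  v_east[!valid] <- 0
  v_north[!valid] <- 0
  if (!all(is.finite(v_east)) || !all(is.finite(v_north)))
    stop("velocity components must be finite")
  structure(list(v_east = v_east, v_north = v_north,
                 lat = as.numeric(lat), lon = as.numeric(lon),
                 valid = valid, method = method, dt = dt),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- sqrt(x$v_east^2 + x$v_north^2)[x$valid]
  cat(sprintf("velocity_field (%s): %d x %d nodes, dt = %g yr\n",
              x$method, nrow(x$v_east), ncol(x$v_east), x$dt))
  cat(sprintf("  valid nodes: %d / %d\n", sum(x$valid), length(x$valid)))
  if (length(sp))
    cat(sprintf("  speed (valid): median %.3f, max %.3f km/yr\n",
                stats::median(sp), max(sp)))
  invisible(x)
}

#' @export
summary.velocity_field <- function(object, ...) {
  sp <- sqrt(object$v_east^2 + object$v_north^2)
  out <- list(method = object$method, dt = object$dt,
              n_nodes = length(object$valid), n_valid = sum(object$valid),
              speed = summary(sp[object$valid]),
              v_east = summary(object$v_east[object$valid]),
              v_north = summary(object$v_north[object$valid]))
  class(out) <- "summary.velocity_field"
  out
}

#' @export
print.summary.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field (%s), dt = %g yr, %d/%d valid nodes\n",
              x$method, x$dt, x$n_valid, x$n_nodes))
  cat("speed (km/yr):\n"); print(x$speed)
  cat("v_east (km/yr):\n"); print(x$v_east)
  cat("v_north (km/yr):\n"); print(x$v_north)
  invisible(x)
}

#' Arrow plot of a velocity field
#'
#' Thins the grid to at most `max_arrows` arrows and draws them in degree
#' space (zonal component divided by `cos(lat)` so headings read correctly).
#'
#' @param x a [velocity_field()].
#' @param scale years of displacement represented by one arrow (default 10).
#' @param max_arrows upper bound on arrows drawn.
#' @param ... passed to [graphics::arrows()].
#' @export
plot.velocity_field <- function(x, scale = 10, max_arrows = 400, ...) {
  step <- max(1L, ceiling(sqrt(length(x$valid) / max_arrows)))
  ii <- seq(1, length(x$lat), by = step)
  jj <- seq(1, length(x$lon), by = step)
  g <- expand.grid(i = ii, j = jj)
  keep <- x$valid[cbind(g$i, g$j)]
  g <- g[keep, , drop = FALSE]
  lat0 <- x$lat[g$i]; lon0 <- x$lon[g$j]
  dlat <- x$v_north[cbind(g$i, g$j)] * scale / KM_PER_DEG
  dlon <- x$v_east[cbind(g$i, g$j)] * scale / km_per_deg_lon(lat0)
  graphics::plot(NA, xlim = range(x$lon), ylim = range(x$lat),
                 xlab = "lon (deg E)", ylab = "lat (deg N)",
                 main = sprintf("climate velocity (%s)", x$method))
  nz <- sqrt(dlat^2 + dlon^2) > 0
  graphics::arrows(lon0[nz], lat0[nz], (lon0 + dlon)[nz], (lat0 + dlat)[nz],
                   length = 0.04, ...)
  invisible(x)
}

#' Velocity at a point (nearest grid node)
#'
#' Looks up the velocity vector at the grid node nearest to the query point.
#' Nearest-node semantics (not interpolation) keep the invalid-node zeroing
#' rule from bleeding into neighbouring values.
#'
#' @param v a [velocity_field()].
#' @param lat,lon query coordinates in degrees (vectorized).
#' @return A data.frame with columns `east`, `north` (km/yr) and `valid`.
#' @export
velocity_at <- function(v, lat, lon) {
  stopifnot(inherits(v, "velocity_field"))
  if (any(lat < min(v$lat) - 1e-12) || any(lat > max(v$lat) + 1e-12) ||
      any(lon < min(v$lon) - 1e-12) || any(lon > max(v$lon) + 1e-12))
    stop("query point outside the velocity-field bounding box")
  dlat <- (max(v$lat) - min(v$lat)) / (length(v$lat) - 1)
  dlon <- (max(v$lon) - min(v$lon)) / (length(v$lon) - 1)
  i <- pmin(pmax(round((lat - v$lat[1]) / dlat), 0), length(v$lat) - 1) + 1L
  j <- pmin(pmax(round((lon - v$lon[1]) / dlon), 0), length(v$lon) - 1) + 1L
  data.frame(east = v$v_east[cbind(i, j)],
             north = v$v_north[cbind(i, j)],
             valid = v$valid[cbind(i, j)])
}

#' @describeIn velocity_at `predict` method: velocity at new locations.
#' @param object a `velocity_field`.
#' @param newdata data.frame with columns `lat` and `lon`.
#' @param ... ignored.
#' @export
predict.velocity_field <- function(object, newdata, ...) {
  velocity_at(object, newdata$lat, newdata$lon)
}
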