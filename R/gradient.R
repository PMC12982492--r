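#' Decadal (window) mean of a yearly field series
#'
#' Node-wise arithmetic mean of the yearly fields whose year falls in the
#' half-open window `[start, end)`. Year-to-year fluctuations in observed
#' climate motivate averaging over 10-year periods before estimating
#' velocities; any window length >= 1 year is accepted.
#'
#' @param series a `field_series` (named list of [gridded_field()], names =
#'   years) as returned by [make_temperature_series()] or [read_field_series()].
#' @param window numeric length-2 half-open year window, e.g. `c(1970, 1980)`.
#' @return A [gridded_field()] with `period = window`.
#' @export
decadal_mean <- function(series, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be [start, end) with end > start")
  years <- as.numeric(names(series))
  use <- which(years >= window[1] & years < window[2])
  if (!length(use)) stop("no years fall in the window")
  f1 <- series[[use[1]]]
  acc <- matrix(0, nrow(f1$values), ncol(f1$values))
  for (k in use) {
    fk <- series[[k]]
    if (!.same_grid(f1, fk)) stop("grid mismatch across years")
    acc <- acc + fk$values
  }
  gridded_field(acc / length(use), f1$lat, f1$lon, period = window,
                units = f1$units)
}

#' Spatial gradient of a gridded field
#'
#' Central differences in degree space (one-sided at edges), converted to
#' physical units with `KM_PER_DEG` km per degree meridionally and
#' `KM_PER_DEG * cos(lat)` zonally. Exact on fields linear in northward
#' distance.
#'
#' @param f a [gridded_field()] of at least 3 x 3 nodes.
#' @return A list with matrices `east` and `north`, both in degC per km.
#' @export
spatial_gradient <- function(f) {
  stopifnot(inherits(f, "gridded_field"))
  v <- f$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("grid must be at least 3 x 3")
  dlat <- (f$lat[nr] - f$lat[1]) / (nr - 1)
  dlon <- (f$lon[nc] - f$lon[1]) / (nc - 1)
  # d/dlat (rows), degrees
  glat <- v
  glat[2:(nr - 1), ] <- (v[3:nr, ] - v[1:(nr - 2), ]) / (2 * dlat)
  glat[1, ] <- (v[2, ] - v[1, ]) / dlat
  glat[nr, ] <- (v[nr, ] - v[nr - 1, ]) / dlat
  # d/dlon (cols), degrees
  glon <- v
  glon[, 2:(nc - 1)] <- (v[, 3:nc] - v[, 1:(nc - 2)]) / (2 * dlon)
  glon[, 1] <- (v[, 2] - v[, 1]) / dlon
  glon[, nc] <- (v[, nc] - v[, nc - 1]) / dlon
  list(east = glon / (KM_PER_DEG * cos(.deg2rad(f$lat))),
       north = glat / KM_PER_DEG)
}

#' Gradient-method climate velocity
#'
#' The classic velocity-of-climate-change index: the temporal rate of change
#' of the field divided by the magnitude of its spatial gradient, directed
#' down-gradient so that warming on a poleward-cooling field yields poleward
#' velocity:
#' \deqn{v = \frac{\partial\psi}{\partial t}\,
#'       \frac{-\nabla\psi}{\lVert\nabla\psi\rVert^2}.}
#' Where the spatial gradient is below `min_grad` the index blows up toward
#' unrealistically large speeds; those nodes are masked invalid and their
#' velocity set to exactly zero, so the output is finite everywhere.
#'
#' The gradient is evaluated on the initial field `f0`; the temporal rate is
#' the node-wise difference divided by the offset between period midpoints.
#'
#' @param f0,f1 initial and final [gridded_field()] on the same grid with
#'   period labels giving `dt > 0`.
#' @param min_grad gradient-magnitude threshold in degC per km below which
#'   nodes are zeroed (default `1e-4`).
#' @return A [velocity_field()] with `method = "gradient"`.
#' @export
gradient_velocity <- function(f0, f1, min_grad = 1e-4) {
  stopifnot(inherits(f0, "gridded_field"), inherits(f1, "gridded_field"))
  if (!.same_grid(f0, f1)) stop("grid mismatch between fields")
  dt <- period_midpoint(f1) - period_midpoint(f0)
  if (dt <= 0) stop("dt must be positive (distinct, ordered period labels)")
  if (min_grad <= 0) stop("min_grad must be positive")
  rate <- (f1$values - f0$values) / dt
  g <- spatial_gradient(f0)
  g2 <- g$east^2 + g$north^2
  ok <- sqrt(g2) >= min_grad
  ve <- vn <- matrix(0, nrow(rate), ncol(rate))
  ve[ok] <- -rate[ok] * g$east[ok] / g2[ok]
  vn[ok] <- -rate[ok] * g$north[ok] / g2[ok]
  velocity_field(ve, vn, f0$lat, f0$lon, valid = ok,
                 method = "gradient", dt = dt)
}
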