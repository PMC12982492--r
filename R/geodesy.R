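#' Weighted geodesic centroid of points on the sphere
#'
#' The geodesic (Frechet/Karcher) mean position: the point minimizing the
#' weighted sum of squared great-circle distances to the observations.
#' Computed by iterating tangent-space averaging (log map at the current
#' estimate, weighted mean, exp map back), started from the normalized
#' weighted vector mean; for the antipode-free clouds arising from species
#' ranges the iteration converges in a handful of steps.
#'
#' @param lat,lon coordinates in degrees (equal-length vectors).
#' @param weights positive weights (observation counts for bird records,
#'   all 1 for presence records). Default all 1.
#' @param tol convergence tolerance on the mean tangent step, radians.
#' @return Named numeric `c(lat, lon)` in degrees.
#' @export
geodesic_centroid <- function(lat, lon, weights = NULL, tol = 1e-14) {
  n <- length(lat)
  if (n == 0) stop("empty point set")
  if (length(lon) != n) stop("lat/lon length mismatch")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights/point length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / sum(weights)
  phi <- .deg2rad(lat); lam <- .deg2rad(lon)
  P <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  m <- colSums(P * w)
  nm <- sqrt(sum(m^2))
  if (nm < 1e-12) stop("degenerate point cloud (zero-norm mean vector)")
  m <- m / nm
  for (it in 1:100) {
    ct <- pmin(pmax(P %*% m, -1), 1)          # cos(angle to current mean)
    theta <- acos(ct)
    # log map: tangent vector of length theta toward each point
    Tn <- P - ct %*% t(m)
    tn <- sqrt(rowSums(Tn^2))
    f <- ifelse(tn > 1e-15, theta / tn, 0)
    step <- colSums(Tn * (w * f))
    ns <- sqrt(sum(step^2))
    if (ns < tol) break
    m <- cos(ns) * m + sin(ns) * step / ns
    m <- m / sqrt(sum(m^2))
  }
  c(lat = .rad2deg(asin(pmin(pmax(m[3], -1), 1))),
    lon = .rad2deg(atan2(m[2], m[1])))
}

#' Decadal centroid of one species' records
#'
#' Records are first averaged within each year (weighted by individual counts
#' in birds mode, unweighted in marine mode), then the yearly centroids are
#' geodesically averaged without weights to give the mean position of the
#' species range over the decade. This two-stage averaging keeps years with
#' many observations from dominating the decade.
#'
#' @param records data.frame with columns `year`, `lat`, `lon` and (birds
#'   mode) `count`; records of a single species.
#' @param decade numeric length-2 half-open year window.
#' @param mode `"birds"` (count-weighted yearly centroids) or `"marine"`.
#' @return Named numeric `c(lat, lon)`.
#' @export
decade_centroid <- function(records, decade, mode = c("birds", "marine")) {
  mode <- match.arg(mode)
  r <- records[records$year >= decade[1] & records$year < decade[2], , drop = FALSE]
  if (!nrow(r)) stop("no records in decade")
  yearly <- lapply(split(r, r$year), function(ry) {
    w <- if (mode == "birds" && !is.null(ry$count)) ry$count else NULL
    geodesic_centroid(ry$lat, ry$lon, w)
  })
  ym <- do.call(rbind, yearly)
  geodesic_centroid(ym[, "lat"], ym[, "lon"])
}

.wrap_lon <- function(dlon) {
  # wrap a longitude difference to (-180, 180]
  w <- (dlon + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Heading of a horizontal vector
#' @param east,north vector components (any consistent unit).
#' @return degrees clockwise from geographic north in `[0, 360)`; `NA` when
#'   the magnitude is zero (heading undefined).
#' @export
heading_of <- function(east, north) {
  h <- (.rad2deg(atan2(east, north))) %% 360
  h[east == 0 & north == 0] <- NA_real_
  h
}

#' Shift vector and per-axis velocities between two centroids
#'
#' The offset between the mean positions during the initial and final decades
#' divided by the time interval. Components use the local equirectangular
#' metric shared with the velocity fields: north km = `KM_PER_DEG * dlat`,
#' east km = `KM_PER_DEG * cos(mean lat) * dlon` (longitude difference
#' wrapped to (-180, 180]). The elevational velocity is the signed elevation
#' difference over time (depth negative, so a deepening shift is negative).
#'
#' @param c0,c1 centroids `c(lat, lon)` in degrees.
#' @param elev0,elev1 elevations in metres at the two centroids (default 0).
#' @param dt time interval in years (> 0).
#' @return A list with `v_east`, `v_north` (km/yr), `v_elev` (m/yr),
#'   `heading` (degrees in `[0, 360)`, `NA` when undefined), `magnitude`
#'   (km/yr) and `heading_defined`.
#' @export
shift_velocity <- function(c0, c1, elev0 = 0, elev1 = 0, dt) {
  if (dt <= 0) stop("dt must be positive")
  north_km <- KM_PER_DEG * (c1[1] - c0[1])
  east_km <- km_per_deg_lon(mean(c(c0[1], c1[1]))) * .wrap_lon(c1[2] - c0[2])
  ve <- unname(east_km / dt)
  vn <- unname(north_km / dt)
  mag <- sqrt(ve^2 + vn^2)
  list(v_east = ve, v_north = vn,
       v_elev = unname((elev1 - elev0) / dt),
       heading = heading_of(ve, vn),
       magnitude = mag,
       heading_defined = mag > 0)
}

#' Displace a point by east/north kilometres
#'
#' Inverse of the metric used by [shift_velocity()]: advances a point in the
#' local equirectangular frame (meridional `KM_PER_DEG`, zonal
#' `KM_PER_DEG * cos(mean lat)` resolved implicitly by a two-pass update).
#'
#' @param lat,lon start coordinates in degrees.
#' @param east_km,north_km displacement in km.
#' @return Named numeric `c(lat, lon)`.
#' @export
displace <- function(lat, lon, east_km, north_km) {
  lat1 <- lat + north_km / KM_PER_DEG
  lon1 <- lon + east_km / km_per_deg_lon((lat + lat1) / 2)
  c(lat = unname(lat1), lon = unname(lon1))
}

#' Centroid tracks for all species over a decade pair
#'
#' Applies [decade_centroid()] to every species present in both decades and
#' converts the centroid offset into per-axis velocities via
#' [shift_velocity()], sampling elevations from a DEM when given.
#'
#' @param records observation records (post-filtering) with columns
#'   `species_id`, `year`, `lat`, `lon`, `count`.
#' @param decade0,decade1 half-open year windows; `dt` is the offset between
#'   their midpoints.
#' @param mode `"birds"` or `"marine"`.
#' @param dem optional [dem_grid()] for elevational velocities.
#' @return A data.frame (one row per species) with centroid positions,
#'   elevations, per-axis velocities, heading and magnitude; class
#'   `centroid_tracks`.
#' @export
centroid_tracks <- function(records, decade0, decade1,
                            mode = c("birds", "marine"), dem = NULL) {
  mode <- match.arg(mode)
  dt <- mean(decade1) - mean(decade0)
  if (dt <= 0) stop("decade1 must follow decade0")
  sp <- sort(unique(records$species_id))
  rows <- lapply(sp, function(s) {
    r <- records[records$species_id == s, , drop = FALSE]
    has0 <- any(r$year >= decade0[1] & r$year < decade0[2])
    has1 <- any(r$year >= decade1[1] & r$year < decade1[2])
    if (!has0 || !has1) return(NULL)
    c0 <- decade_centroid(r, decade0, mode)
    c1 <- decade_centroid(r, decade1, mode)
    e0 <- if (!is.null(dem)) sample_elevation(dem, c0[1], c0[2]) else 0
    e1 <- if (!is.null(dem)) sample_elevation(dem, c1[1], c1[2]) else 0
    v <- shift_velocity(c0, c1, e0, e1, dt)
    data.frame(species_id = s,
               decade0 = sprintf("%g-%g", decade0[1], decade0[2]),
               decade1 = sprintf("%g-%g", decade1[1], decade1[2]),
               lat0 = unname(c0[1]), lon0 = unname(c0[2]),
               lat1 = unname(c1[1]), lon1 = unname(c1[2]),
               elev0 = unname(e0), elev1 = unname(e1),
               v_lon_kmyr = v$v_east, v_lat_kmyr = v$v_north,
               v_elev_myr = v$v_elev,
               heading_deg = v$heading, magnitude_kmyr = v$magnitude,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species_id = character(), decade0 = character(),
                      decade1 = character(), lat0 = numeric(), lon0 = numeric(),
                      lat1 = numeric(), lon1 = numeric(), elev0 = numeric(),
                      elev1 = numeric(), v_lon_kmyr = numeric(),
                      v_lat_kmyr = numeric(), v_elev_myr = numeric(),
                      heading_deg = numeric(), magnitude_kmyr = numeric(),
                      stringsAsFactors = FALSE)
  attr(out, "dt") <- dt
  class(out) <- c("centroid_tracks", "data.frame")
  out
}
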