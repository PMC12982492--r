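#' Synthetic temperature-field scenario
#'
#' Describes an idealized gridded temperature series with a known closed form,
#' used to exercise the velocity estimators under controlled isotherm
#' geometries: straight parallel isotherms, curved isotherms, a locally flat
#' (near-zero-gradient) patch, or curvature plus a flat patch (`composite`).
#'
#' The generated field is
#' \deqn{\psi(lat, lon, t) = \psi_0 - a d(lat) + c \sin(k (lon - lon_0)) +
#'       b (1 + m \sin(k_b (lon - lon_0))) t}
#' where `d(lat)` is the northward distance in km from the southern edge,
#' `a` the meridional gradient (degC/km), `b` the warming rate (degC/yr),
#' `c`/`k` the curvature amplitude (degC) and wavenumber (rad per degree of
#' longitude, zero for `parallel`), and `m`/`k_b` an optional longitudinal
#' modulation of the warming rate (so the true isotherm displacement varies
#' smoothly in space while staying purely meridional). Inside a flat patch the
#' spatial part is frozen at its value at the patch centre, so the spatial
#' gradient vanishes there.
#'
#' @param name one of `"parallel"`, `"curved"`, `"flat_patch"`, `"composite"`.
#' @param lat_range,lon_range numeric length-2 extents in degrees.
#' @param spacing grid spacing in degrees (> 0), same for both axes.
#' @param a meridional gradient in degC per km (default 0.01).
#' @param b secular warming rate in degC per yr (default 0.02).
#' @param psi0 field value at the south edge at t = 0 (degC).
#' @param curve_amp,curve_k curvature amplitude (degC) and wavenumber
#'   (rad/degree of longitude); used by `curved` and `composite`.
#' @param warm_mod_amp,warm_mod_k relative amplitude and wavenumber of the
#'   longitudinal warming-rate modulation (defaults 0 = uniform warming).
#' @param patch_center c(lat, lon) of the flat patch centre (defaults to the
#'   domain centre); `patch_radius` in grid cells.
#' @param years integer years covered, e.g. `1960:1979`.
#' @return An object of class `field_scenario`.
#' @seealso [make_temperature_series()], [scenario_value()]
#' @export
field_scenario <- function(name = c("parallel", "curved", "flat_patch", "composite"),
                           lat_range = c(35, 50), lon_range = c(-120, -95),
                           spacing = 0.5, a = 0.01, b = 0.02, psi0 = 15,
                           curve_amp = 2, curve_k = 0.3,
                           warm_mod_amp = 0, warm_mod_k = 0.2,
                           patch_center = NULL, patch_radius = 4,
                           years = 1960:1979) {
  name <- match.arg(name)
  if (spacing <= 0) stop("spacing must be positive")
  if (length(years) < 2) stop("at least 2 years required")
  lat <- seq(lat_range[1], lat_range[2], by = spacing)
  lon <- seq(lon_range[1], lon_range[2], by = spacing)
  if (length(lat) < 3 || length(lon) < 3) stop("grid must be at least 3 x 3")
  if (is.null(patch_center)) patch_center <- c(mean(lat), mean(lon))
  structure(list(name = name, lat = lat, lon = lon, spacing = spacing,
                 a = a, b = b, psi0 = psi0,
                 curve_amp = if (name %in% c("curved", "composite")) curve_amp else 0,
                 curve_k = curve_k,
                 warm_mod_amp = warm_mod_amp, warm_mod_k = warm_mod_k,
                 patch_center = patch_center, patch_radius = patch_radius,
                 has_patch = name %in% c("flat_patch", "composite"),
                 years = as.integer(years)),
            class = "field_scenario")
}

# spatial (time-independent) part of the scenario field at arbitrary coords
.scenario_spatial <- function(sc, lat, lon) {
  d_km <- KM_PER_DEG * (lat - sc$lat[1])
  sc$psi0 - sc$a * d_km + sc$curve_amp * sin(sc$curve_k * (lon - sc$lon[1]))
}

# local warming rate (degC/yr), possibly modulated along longitude
.scenario_rate <- function(sc, lon) {
  sc$b * (1 + sc$warm_mod_amp * sin(sc$warm_mod_k * (lon - sc$lon[1])))
}

#' Closed-form value of a scenario field
#'
#' Evaluates the generating formula of a [field_scenario()] at arbitrary
#' coordinates and time; the analytic reference for the generated grids.
#'
#' @param sc a `field_scenario`.
#' @param lat,lon coordinates in degrees (vectorized, recycled).
#' @param year calendar year; time is measured from the scenario's first year.
#' @return field value(s) in degC.
#' @export
scenario_value <- function(sc, lat, lon, year) {
  t <- year - sc$years[1]
  v <- .scenario_spatial(sc, lat, lon) + .scenario_rate(sc, lon) * t
  if (sc$has_patch) {
    inside <- .in_patch(sc, lat, lon)
    vc <- sc$psi0 - sc$a * KM_PER_DEG * (sc$patch_center[1] - sc$lat[1]) +
      sc$curve_amp * sin(sc$curve_k * (sc$patch_center[2] - sc$lon[1]))
    v[inside] <- vc + (.scenario_rate(sc, lon) * t)[inside]
  }
  v
}

.in_patch <- function(sc, lat, lon) {
  r_deg <- sc$patch_radius * sc$spacing
  sqrt((lat - sc$patch_center[1])^2 + (lon - sc$patch_center[2])^2) <= r_deg + 1e-12
}

#' Generate a yearly temperature series from a scenario
#'
#' One [gridded_field()] per year, evaluated from the scenario's closed form
#' at every node, so decadal averaging and both velocity estimators can be
#' exercised against known ground truth.
#'
#' @param sc a [field_scenario()].
#' @return A named list of `gridded_field` objects, names = years; class
#'   `field_series`.
#' @export
make_temperature_series <- function(sc) {
  stopifnot(inherits(sc, "field_scenario"))
  grid <- expand.grid(lat = sc$lat, lon = sc$lon)
  out <- lapply(sc$years, function(y) {
    v <- matrix(scenario_value(sc, grid$lat, grid$lon, y),
                nrow = length(sc$lat), ncol = length(sc$lon))
    gridded_field(v, sc$lat, sc$lon, period = y)
  })
  names(out) <- sc$years
  class(out) <- c("field_series", "list")
  out
}

#' Generate a synthetic digital elevation model
#'
#' @param kind `"flat"` (all zeros), `"linear_slope"` (elevation grows
#'   northward at `slope` m per km), or `"ridge"` (a crest at the mid
#'   latitude, sloping down on both sides at `slope` m per km).
#' @param lat_range,lon_range,spacing grid spec in degrees.
#' @param slope metres per km of northward distance.
#' @param ridge_height crest height in metres (ridge only).
#' @return A [dem_grid()].
#' @export
make_dem <- function(kind = c("flat", "linear_slope", "ridge"),
                     lat_range = c(35, 50), lon_range = c(-120, -95),
                     spacing = 0.5, slope = 5, ridge_height = 2000) {
  kind <- match.arg(kind)
  if (spacing <= 0) stop("spacing must be positive")
  lat <- seq(lat_range[1], lat_range[2], by = spacing)
  lon <- seq(lon_range[1], lon_range[2], by = spacing)
  d_km <- KM_PER_DEG * (lat - lat[1])
  row_elev <- switch(kind,
    flat = rep(0, length(lat)),
    linear_slope = slope * d_km,
    ridge = ridge_height - slope * abs(d_km - d_km[length(d_km)] / 2))
  dem_grid(matrix(row_elev, nrow = length(lat), ncol = length(lon)), lat, lon)
}
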