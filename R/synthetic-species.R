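#' Synthetic species-observation scenario
#'
#' Describes a set of simulated species whose true range centroids are
#' advected by a known velocity (a prescribed vector or a fitted
#' [velocity_field()]) with a tunable tracking factor, observed through
#' yearly site clouds. Each species has a fixed roster of sites; every year
#' each site is placed i.i.d. Gaussian (in local km coordinates) around the
#' moving true centroid and contributes `obs_per_site_year` observation
#' records. Bird-mode records carry individual counts (Poisson, clipped to
#' >= 1); marine-mode records carry a presence flag.
#'
#' A configurable fraction of species and of sites is engineered to fail the
#' inclusion criteria (a species under-reported in one year; a site with a
#' single observation in one year), so the filters have both positive and
#' negative cases.
#'
#' @param n_species number of species.
#' @param n_sites observation sites per species.
#' @param obs_per_site_year observations of a species at a site per year
#'   (default 2, the site-rule minimum).
#' @param mode `"birds"` (counts) or `"marine"` (presence).
#' @param count_mean Poisson mean of individual counts (birds mode, >= 1).
#' @param tracking tracking factor s in `[0, 1]`: 1 = centroids follow the
#'   local climate velocity perfectly, 0 = stationary.
#' @param noise_sd positional noise (site-cloud standard deviation) in km.
#' @param species_drift_sd standard deviation (km/yr) of a per-species
#'   constant northward velocity offset (species-level random intercept
#'   structure for the mixed-model analyses); default 0.
#' @param lat_range,lon_range box in which initial centroids are scattered.
#' @param fail_species_frac,fail_site_frac fractions of species / sites
#'   engineered to fail the inclusion criteria.
#' @param seed integer RNG seed; identical seeds and scenarios give
#'   byte-identical record sets.
#' @return An object of class `species_scenario`.
#' @export
species_scenario <- function(n_species = 20, n_sites = 5, obs_per_site_year = 2,
                             mode = c("birds", "marine"), count_mean = 3,
                             tracking = 1, noise_sd = 10,
                             species_drift_sd = 0,
                             lat_range = c(38, 47), lon_range = c(-115, -100),
                             fail_species_frac = 0, fail_site_frac = 0,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (tracking < 0 || tracking > 1) stop("tracking factor must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (count_mean < 1) stop("count_mean must be >= 1")
  structure(list(n_species = n_species, n_sites = n_sites,
                 obs_per_site_year = obs_per_site_year, mode = mode,
                 count_mean = count_mean, tracking = tracking,
                 noise_sd = noise_sd, species_drift_sd = species_drift_sd,
                 lat_range = lat_range, lon_range = lon_range,
                 fail_species_frac = fail_species_frac,
                 fail_site_frac = fail_site_frac, seed = as.integer(seed)),
            class = "species_scenario")
}

# velocity experienced at a point: prescribed c(east, north) or nearest-node
# lookup in a velocity_field
.local_velocity <- function(velocity, lat, lon) {
  if (inherits(velocity, "velocity_field")) {
    v <- velocity_at(velocity, lat, lon)
    c(v$east, v$north)
  } else {
    c(velocity[1], velocity[2])
  }
}

#' Generate synthetic species observation records
#'
#' Simulates yearly observation records for every species of a
#' [species_scenario()]: the true centroid is advected yearly at
#' `tracking * v(centroid)` (velocity looked up at the current centroid,
#' nearest node) plus any per-species drift, and the year's site cloud is
#' drawn around it. The true centroid trajectory of every species is
#' returned in `attr(, "truth")` for parameter-recovery checks.
#'
#' @param scenario a [species_scenario()].
#' @param velocity a [velocity_field()] or a prescribed `c(east, north)`
#'   vector in km/yr.
#' @param years integer years to simulate.
#' @return data.frame with columns `species_id`, `site_id`, `year`, `lat`,
#'   `lon`, `count` (NA in marine mode), `presence` (0/1; 1 in marine mode,
#'   NA in birds mode).
#' @export
make_species_records <- function(scenario, velocity, years) {
  stopifnot(inherits(scenario, "species_scenario"))
  years <- as.integer(years)
  set.seed(scenario$seed)
  ns <- scenario$n_species
  sp_ids <- sprintf("sp%03d", seq_len(ns))
  lat0 <- stats::runif(ns, scenario$lat_range[1], scenario$lat_range[2])
  lon0 <- stats::runif(ns, scenario$lon_range[1], scenario$lon_range[2])
  drift <- if (scenario$species_drift_sd > 0)
    stats::rnorm(ns, 0, scenario$species_drift_sd) else rep(0, ns)

  n_fail_sp <- round(scenario$fail_species_frac * ns)
  fail_sp <- seq_len(ns) <= n_fail_sp          # deterministic choice
  fail_sp_year <- years[1 + (seq_len(ns) %% length(years))][fail_sp]
  n_fail_site <- round(scenario$fail_site_frac * scenario$n_sites)

  out <- vector("list", ns)
  truth <- vector("list", ns)
  for (s in seq_len(ns)) {
    lat <- lat0[s]; lon <- lon0[s]
    fail_year <- if (fail_sp[s]) fail_sp_year[sum(fail_sp[1:s])] else NA_integer_
    rows <- vector("list", length(years))
    tr <- matrix(NA_real_, length(years), 2)
    for (yi in seq_along(years)) {
      y <- years[yi]
      tr[yi, ] <- c(lat, lon)
      # which sites report, and how often, this year
      n_sites <- scenario$n_sites
      obs_per <- rep(scenario$obs_per_site_year, n_sites)
      if (n_fail_site > 0 && yi == 1 + (s %% length(years)) &&
          scenario$mode == "birds")
        obs_per[seq_len(n_fail_site)] <- 1L   # breaks the >= 2/site/year rule
      if (!is.na(fail_year) && y == fail_year) {
        # under-report the species this year: fewer than the species minimum
        target <- if (scenario$mode == "birds") 4L else 2L
        obs_per <- rep(0L, n_sites)
        k <- 1
        left <- target
        while (left > 0) {
          add <- min(left, scenario$obs_per_site_year)
          obs_per[k] <- add
          left <- left - add
          k <- k + 1
        }
      }
      n_obs <- sum(obs_per)
      if (n_obs > 0) {
        site_id <- rep(sprintf("%s_site%02d", sp_ids[s], seq_len(n_sites)),
                       times = obs_per)
        dn <- stats::rnorm(n_obs, 0, scenario$noise_sd)
        de <- stats::rnorm(n_obs, 0, scenario$noise_sd)
        olat <- lat + dn / KM_PER_DEG
        olon <- lon + de / km_per_deg_lon(lat)
        count <- if (scenario$mode == "birds")
          pmax(1L, stats::rpois(n_obs, scenario$count_mean)) else NA_integer_
        rows[[yi]] <- data.frame(
          species_id = sp_ids[s], site_id = site_id, year = y,
          lat = olat, lon = olon, count = count,
          presence = if (scenario$mode == "marine") 1L else NA_integer_,
          stringsAsFactors = FALSE)
      }
      # advect the true centroid to next year
      v <- .local_velocity(velocity, lat, lon)
      vn <- scenario$tracking * v[2] + drift[s]
      ve <- scenario$tracking * v[1]
      lat <- lat + vn / KM_PER_DEG
      lon <- lon + ve / km_per_deg_lon(lat)
    }
    out[[s]] <- do.call(rbind, rows)
    truth[[s]] <- data.frame(species_id = sp_ids[s], year = years,
                             lat = tr[, 1], lon = tr[, 2],
                             engineered_fail = fail_sp[s],
                             stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  attr(records, "truth") <- do.call(rbind, truth)
  attr(records, "scenario") <- scenario
  records
}
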