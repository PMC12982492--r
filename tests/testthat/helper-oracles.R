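# Independent brute-force oracles used to check the implementation.
# Deliberately written with naive nested loops / generic optimizers so they
# share no code path with the package.

# --- inclusion-filter oracle ------------------------------------------------
# Nested loops over species x site x year; mirrors the documented rules:
# birds: drop (species, site) pairs lacking >= 2 obs in any required year,
# then keep species with >= 5 reports in every required year (counted on the
# surviving records); marine: species with >= 3 obs in every required year.
oracle_filter <- function(records, decade0, decade1, mode) {
  yrs <- c(seq(decade0[1], decade0[2] - 1), seq(decade1[1], decade1[2] - 1))
  keep_row <- rep(TRUE, nrow(records))
  in_win <- records$year %in% yrs
  if (mode == "birds") {
    for (sp in unique(records$species_id)) {
      sp_rows <- records$species_id == sp
      for (site in unique(records$site_id[sp_rows])) {
        pr <- sp_rows & records$site_id == site
        ok <- TRUE
        for (y in yrs) if (sum(pr & records$year == y) < 2) { ok <- FALSE; break }
        if (!ok) keep_row[pr] <- FALSE
      }
    }
    surviving <- records[keep_row, , drop = FALSE]
    for (sp in unique(records$species_id)) {
      ok <- TRUE
      for (y in yrs)
        if (sum(surviving$species_id == sp & surviving$year == y) < 5) {
          ok <- FALSE; break
        }
      if (!ok) keep_row[records$species_id == sp] <- FALSE
    }
  } else {
    for (sp in unique(records$species_id)) {
      ok <- TRUE
      for (y in yrs)
        if (sum(records$species_id == sp & records$year == y) < 3) {
          ok <- FALSE; break
        }
      if (!ok) keep_row[records$species_id == sp] <- FALSE
    }
  }
  records[keep_row, , drop = FALSE]
}

# --- geodesic-centroid oracle ----------------------------------------------
# Direct minimization of the weighted sum of squared great-circle distances
# (haversine; argmin is radius-invariant).
oracle_centroid <- function(lat, lon, weights = rep(1, length(lat))) {
  obj <- function(p) {
    d <- geosphere::distHaversine(cbind(lon, lat), c(p[2], p[1]))
    sum(weights * d^2)
  }
  start <- c(mean(lat), mean(lon))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(lat = fit$par[1], lon = fit$par[2])
}

# --- closed-form OLS oracle -------------------------------------------------
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  res <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  list(slope = slope, se = se, r = r)
}

# --- von Mises sampler (Best & Fisher rejection scheme) ---------------------
rvonmises_deg <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  (mu_deg + out * 180 / pi + 180) %% 360 - 180
}

# --- shared fixtures --------------------------------------------------------
# 30 x 30 parallel-isotherm scenario (a = 0.01 degC/km, b = 0.02 degC/yr)
parallel_scenario_30 <- function() {
  field_scenario("parallel", lat_range = c(35, 49.5),
                 lon_range = c(-110, -95.5), spacing = 0.5,
                 a = 0.01, b = 0.02, years = 1960:1979)
}

# curved isotherms + longitudinally modulated warming; the true deformation
# (a purely meridional shift varying smoothly with longitude) is on-grid.
# Curvature strong enough that the down-gradient direction is badly wrong
# over part of the domain — the regime where the two estimators disagree.
curved_scenario <- function() {
  field_scenario("curved", lat_range = c(35, 49.5), lon_range = c(-110, -95.5),
                 spacing = 0.5, a = 0.01, b = 0.02, curve_amp = 5,
                 curve_k = 0.4, warm_mod_amp = 0.5, warm_mod_k = 0.35,
                 years = 1960:1979)
}

decade_pair_fields <- function(sc) {
  series <- make_temperature_series(sc)
  list(f0 = decadal_mean(series, c(1960, 1970)),
       f1 = decadal_mean(series, c(1970, 1980)))
}

interior <- function(m, margin = 2) {
  m[(1 + margin):(nrow(m) - margin), (1 + margin):(ncol(m) - margin)]
}

# comparison rows from tracks against one or two prescribed fields, reusing
# the package surface only (build_comparison slots)
rows_against <- function(tracks, field_a, field_b = NULL, dem = NULL) {
  build_comparison(tracks, vgrad = field_a, vmatch = field_b, dem = dem)
}
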