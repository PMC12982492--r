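test_that("filters match the brute-force oracle on an engineered fixture", {
  d0 <- c(1960, 1970); d1 <- c(1970, 1980)
  sc <- species_scenario(n_species = 20, fail_species_frac = 0.2,
                         fail_site_frac = 0.2, noise_sd = 10, seed = 21)
  r <- make_species_records(sc, c(1, 2), 1960:1979)
  expect_identical(filter_birds(r, d0, d1), oracle_filter(r, d0, d1, "birds"))

  scm <- species_scenario(n_species = 20, mode = "marine", n_sites = 3,
                          obs_per_site_year = 1, fail_species_frac = 0.25,
                          noise_sd = 10, seed = 22)
  rm_ <- make_species_records(scm, c(1, 2), 1960:1979)
  expect_identical(filter_marine(rm_, d0, d1),
                   oracle_filter(rm_, d0, d1, "marine"))
  # engineered failures really are removed
  expect_lt(length(unique(filter_marine(rm_, d0, d1)$species_id)), 20)
})

test_that("bird filter edge cases: exactly 5 reports pass, 4 fail, bad sites drop", {
  d0 <- c(1970, 1972); d1 <- c(1974, 1976)
  yrs <- c(1970:1971, 1974:1975)
  mk <- function(sp, site, year, n) {
    data.frame(species_id = sp, site_id = site, year = rep(year, n),
               lat = 40, lon = -100, count = 1L, presence = NA_integer_)
  }
  # spA: 5 reports each year via sites a1 (3) + a2 (2) -> retained
  recs <- do.call(rbind, c(
    lapply(yrs, function(y) mk("spA", "a1", y, 3)),
    lapply(yrs, function(y) mk("spA", "a2", y, 2)),
    # spB: 4 reports in one initial-decade year -> removed
    lapply(yrs, function(y) mk("spB", "b1", y, if (y == 1970) 4 else 5)),
    # spC: site c2 misses a year; site c1 alone still gives 5/yr -> species kept
    lapply(yrs, function(y) mk("spC", "c1", y, 5)),
    lapply(setdiff(yrs, 1975), function(y) mk("spC", "c2", y, 2))))
  kept <- filter_birds(recs, d0, d1)
  expect_setequal(unique(kept$species_id), c("spA", "spC"))
  expect_false("c2" %in% kept$site_id[kept$species_id == "spC"])
  expect_identical(kept, oracle_filter(recs, d0, d1, "birds"))
  # overlapping decades rejected; empty input passes through empty
  expect_error(filter_birds(recs, c(1970, 1975), c(1974, 1976)), "disjoint")
  expect_equal(nrow(filter_marine(recs[0, ], d0, d1)), 0)
})

test_that("marine filter keeps exactly-3-per-year species and drops 2-in-one-year", {
  d0 <- c(1970, 1972); d1 <- c(1974, 1976)
  yrs <- c(1970:1971, 1974:1975)
  mk <- function(sp, year, n)
    data.frame(species_id = sp, site_id = "s", year = rep(year, n),
               lat = 40, lon = -100, count = NA_integer_, presence = 1L)
  recs <- do.call(rbind, c(
    lapply(yrs, function(y) mk("ok3", y, 3)),
    lapply(yrs, function(y) mk("low", y, if (y == 1974) 2 else 3))))
  kept <- filter_marine(recs, d0, d1)
  expect_setequal(unique(kept$species_id), "ok3")
})

test_that("geodesic centroid matches symmetry, weighting and the Frechet oracle", {
  expect_equal(geodesic_centroid(c(10, -10), c(0, 0)),
               c(lat = 0, lon = 0), tolerance = 1e-12)
  expect_equal(geodesic_centroid(47.3, 8.5), c(lat = 47.3, lon = 8.5))
  w <- geodesic_centroid(c(0, 0), c(0, 10), weights = c(3, 1))
  expect_equal(unname(w["lon"]), 2.5, tolerance = 0.01)
  # permutation invariance and centroid-point absorption
  set.seed(1)
  la <- runif(8, 30, 45); lo <- runif(8, -110, -95); ww <- runif(8, 0.5, 4)
  c1 <- geodesic_centroid(la, lo, ww)
  p <- sample(8)
  expect_equal(geodesic_centroid(la[p], lo[p], ww[p]), c1, tolerance = 1e-10)
  expect_equal(geodesic_centroid(c(la, c1["lat"]), c(lo, c1["lon"]),
                                 c(ww, 5)), c1, tolerance = 1e-8)

  skip_if_not_installed("geosphere")
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    clat <- runif(1, -30, 50); clon <- runif(1, -150, 150)
    la <- clat + runif(n, -15, 15)
    lo <- clon + runif(n, -15, 15)
    ww <- runif(n, 0.5, 5)
    got <- geodesic_centroid(la, lo, ww)
    want <- oracle_centroid(la, lo, ww)
    expect_lt(max(abs(got - want)), 0.01)
  }
  expect_error(geodesic_centroid(numeric(), numeric()), "empty")
  expect_error(geodesic_centroid(c(0, 0), c(0, 180)), "degenerate")
})

test_that("decade centroid averages yearly centroids, not raw records", {
  # two years, second year has many records at one spot: yearly averaging
  # keeps it from dominating
  recs <- data.frame(
    species_id = "sp", site_id = "s", year = c(1970, rep(1971, 9)),
    lat = c(0, rep(2, 9)), lon = 0, count = 1L, presence = NA_integer_)
  cc <- decade_centroid(recs, c(1970, 1980), mode = "birds")
  expect_equal(unname(cc["lat"]), 1, tolerance = 1e-9)
  expect_error(decade_centroid(recs, c(1950, 1960)), "no records")
})

test_that("shift_velocity decomposes the offset in the shared metric", {
  v <- shift_velocity(c(40, -100), c(41, -100), dt = 10)
  expect_equal(v$v_north, KM_PER_DEG / 10, tolerance = 1e-12)  # 11.12 km/yr
  expect_equal(v$v_east, 0)
  expect_equal(v$heading, 0)

  e <- shift_velocity(c(40, -100), c(40, -99), dt = 10)
  expect_equal(e$heading, 90)
  expect_equal(e$v_east, km_per_deg_lon(40) / 10, tolerance = 1e-12)

  z <- shift_velocity(c(40, -100), c(40, -100), elev0 = 5, elev1 = 5, dt = 10)
  expect_equal(z$magnitude, 0)
  expect_equal(z$v_elev, 0)
  expect_false(z$heading_defined)
  expect_true(is.na(z$heading))
  expect_error(shift_velocity(c(40, -100), c(41, -100), dt = 0), "positive")

  # magnitude^2 = east^2 + north^2, and the elevational sign convention
  d <- shift_velocity(c(40, -100), c(41, -99), elev0 = -100, elev1 = -180,
                      dt = 10)
  expect_equal(d$magnitude^2, d$v_east^2 + d$v_north^2, tolerance = 1e-12)
  expect_equal(d$v_elev, -8)  # deepening is negative

  # round trip through the same metric recovers the endpoint
  c1 <- displace(40, -100, d$v_east * 10, d$v_north * 10)
  expect_equal(unname(c1), c(41, -99), tolerance = 1e-6)
})

test_that("bilinear DEM sampling: nodes exact, midpoints average straddling nodes", {
  ridge <- make_dem("ridge", slope = 5, spacing = 0.5)
  expect_equal(sample_elevation(ridge, ridge$lat[4], ridge$lon[7]),
               ridge$values[4, 7])
  mid <- sample_elevation(ridge, (ridge$lat[4] + ridge$lat[5]) / 2, ridge$lon[7])
  expect_equal(mid, mean(ridge$values[4:5, 7]), tolerance = 1e-12)
  expect_error(sample_elevation(ridge, 80, -100), "outside")
})

test_that("drifting synthetic species recover the imposed track within noise", {
  sc <- species_scenario(n_species = 6, tracking = 1, noise_sd = 5,
                         n_sites = 8, seed = 9)
  r <- make_species_records(sc, c(1.5, 2.5), 1960:1979)
  tracks <- centroid_tracks(r, c(1960, 1970), c(1970, 1980), mode = "birds")
  # 8 sites x 2 obs x 10 yr ~ sd of decade centroid ~ 5/sqrt(160) km
  expect_equal(tracks$v_lat_kmyr, rep(2.5, 6), tolerance = 0.2)
  expect_equal(tracks$v_lon_kmyr, rep(1.5, 6), tolerance = 0.2)
})
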