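# build bare comparison rows for unit-testing the fitting layer
fake_rows <- function(x, y, species = paste0("sp", seq_along(x)),
                      prefix = "grad") {
  d <- data.frame(species_id = species, pair = "p", region = "west",
                  sp_v_lon = 0, sp_v_lat = y, sp_v_elev = 0,
                  sp_heading = NA_real_, stringsAsFactors = FALSE)
  d[[paste0(prefix, "_v_lon")]] <- 0
  d[[paste0(prefix, "_v_lat")]] <- x
  d[[paste0(prefix, "_v_elev")]] <- 0
  d[[paste0(prefix, "_valid")]] <- TRUE
  d[[paste0(prefix, "_heading_diff")]] <- NA_real_
  d
}

test_that("component_fit equals the closed-form OLS oracle", {
  set.seed(10)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.3)
  f <- component_fit(fake_rows(x, y), "lat", "gradient")
  o <- oracle_ols(x, y)
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$se, o$se, tolerance = 1e-10)
  expect_equal(f$r, o$r, tolerance = 1e-10)
  # perfect line
  fp <- component_fit(fake_rows(1:10, 1:10), "lat", "gradient")
  expect_equal(fp$slope, 1, tolerance = 1e-12)
  expect_equal(fp$r, 1, tolerance = 1e-12)
})

test_that("outlier threshold removes extreme components, idempotently", {
  x <- c(rnorm(20), 1500); y <- c(rnorm(20), 0.5)
  f <- component_fit(fake_rows(x, y), "lat", "gradient",
                     outlier_threshold = 1000)
  expect_equal(f$n_removed, 1)
  expect_equal(f$n_used + f$n_removed, 21)
  # removing the outlier first changes nothing (idempotent, order-free)
  f2 <- component_fit(fake_rows(x[1:20], y[1:20]), "lat", "gradient",
                      outlier_threshold = 1000)
  expect_equal(f$slope, f2$slope, tolerance = 1e-12)
  # extreme species component removed too
  f3 <- component_fit(fake_rows(c(rnorm(20), 0.5), c(rnorm(20), -2000)),
                      "lat", "gradient")
  expect_equal(f3$n_removed, 1)
  expect_error(component_fit(fake_rows(c(0, 1), c(0, 1)), "lat", "gradient"),
               "fewer than 3")
})

test_that("heading differences wrap to [-180, 180) and compose as stated", {
  expect_equal(heading_difference(350, 10), -20)
  expect_equal(heading_difference(10, 10), 0)
  expect_equal(heading_difference(0, 180), -180)
  set.seed(2)
  h1 <- runif(1e4, 0, 360); h2 <- runif(1e4, 0, 360)
  d <- heading_difference(h1, h2)
  expect_true(all(d >= -180 & d < 180))
  # wrap(wrap(x)) = wrap(x)
  expect_equal(heading_difference(d, 0), d, tolerance = 1e-12)
  expect_true(is.na(heading_difference(NA, 10)))
})

test_that("mixed model recovers a known slope with species random intercepts", {
  set.seed(30)
  ns <- 100; per <- 5
  sp <- rep(sprintf("sp%03d", 1:ns), each = per)
  b <- rep(rnorm(ns, 0, 0.5), each = per)
  x <- rnorm(ns * per, 0, 2)
  y <- 0.3 + b + 1.0 * x + rnorm(ns * per, 0, 0.4)
  f <- mixed_fit(fake_rows(x, y, species = sp), "lat", "gradient")
  expect_lt(abs(f$estimate - 1), 3 * f$se)
  expect_gt(f$ranef_var, 0.1)
  expect_equal(f$n_groups, ns)
  expect_gt(f$z, 10)
})

test_that("zero-variance groups with a perfect line degenerate to OLS slope 1", {
  x <- rep(seq(-2, 2, length.out = 10), 3)
  sp <- rep(c("a", "b", "c"), each = 10)
  f <- mixed_fit(fake_rows(x, x, species = sp), "lat", "gradient")
  expect_equal(f$estimate, 1, tolerance = 1e-6)
  expect_true(f$singular)
})

test_that("mixed-model slope test is near-nominal under the null", {
  # one observation per species, pure noise: type-I error at alpha = 0.05
  # should be in [0.01, 0.10] over 200 seeded replicates
  set.seed(77)
  rej <- 0L
  for (i in 1:200) {
    x <- rnorm(200); y <- rnorm(200)
    f <- mixed_fit(fake_rows(x, y), "lat", "gradient")
    if (f$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.10)
})

test_that("multilinear fit recovers coefficients and flags collinearity", {
  # orthogonal regressors, zero noise: exact recovery
  n <- 40
  v_lon <- rep(c(-1, 1), n / 2)
  v_lat <- rep(c(-1, -1, 1, 1), n / 4)
  v_elev <- rep(c(-1, 1, 1, -1), n / 4)
  rows <- fake_rows(v_lat, 2 * v_lat - 0.5 * v_lon + 0.25 * v_elev)
  rows$grad_v_lon <- v_lon; rows$grad_v_elev <- v_elev
  f <- multilinear_fit(rows, "lat", "gradient")
  est <- f$coefficients$estimate[match(c("v_lon", "v_lat", "v_elev"),
                                       f$coefficients$term)]
  expect_equal(est, c(-0.5, 2, 0.25), tolerance = 1e-10)
  expect_false(f$rank_deficient)

  # only a latitudinal effect: other coefficients within 3 SE of zero
  set.seed(4)
  rows2 <- fake_rows(rnorm(200), 0)
  rows2$grad_v_lon <- rnorm(200); rows2$grad_v_elev <- rnorm(200)
  rows2$sp_v_lat <- 0.8 * rows2$grad_v_lat + rnorm(200, 0, 0.2)
  f2 <- multilinear_fit(rows2, "lat", "gradient")
  cf <- f2$coefficients
  for (term in c("v_lon", "v_elev")) {
    k <- match(term, cf$term)
    expect_lt(abs(cf$estimate[k]), 3 * cf$se[k])
  }

  # collinear regressors are flagged
  rows3 <- fake_rows(rnorm(30), rnorm(30))
  rows3$grad_v_lon <- 2 * rows3$grad_v_lat
  rows3$grad_v_elev <- rnorm(30)
  expect_true(multilinear_fit(rows3, "lat", "gradient")$rank_deficient)
})

test_that("heading summary: degenerate, antipodal and von Mises cases", {
  r0 <- fake_rows(1:5, 1:5)
  r0$grad_heading_diff <- 0
  s0 <- heading_summary(r0, "gradient")
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)

  r2 <- fake_rows(1:2, 1:2)
  r2$grad_heading_diff <- c(90, -90)
  s2 <- heading_summary(r2, "gradient")
  expect_true(is.na(s2$mean))
  expect_lt(s2$resultant, 1e-12)

  set.seed(8)
  dd <- rvonmises_deg(500, 20, 4)
  rv <- fake_rows(seq_along(dd), seq_along(dd))
  rv$grad_heading_diff <- dd
  sv <- heading_summary(rv, "gradient")
  expect_lt(abs(sv$mean - 20), 3)
  expect_equal(sum(sv$counts), 500)
})

test_that("build_comparison samples fields at the initial centroid and flags masks", {
  sc <- field_scenario("flat_patch", patch_radius = 5, years = 1960:1979)
  p <- decade_pair_fields(sc)
  vg <- gradient_velocity(p$f0, p$f1)
  dem <- make_dem("linear_slope", slope = 5)

  # one track centred in the masked patch, one in the clean south-west
  tracks <- data.frame(
    species_id = c("masked", "clean"),
    decade0 = "1960-1970", decade1 = "1970-1980",
    lat0 = c(sc$patch_center[1], 37), lon0 = c(sc$patch_center[2], -117),
    lat1 = c(sc$patch_center[1], 37.2), lon1 = c(sc$patch_center[2], -117),
    elev0 = 0, elev1 = 0, v_lon_kmyr = 0,
    v_lat_kmyr = c(0, 2.2), v_elev_myr = 0,
    heading_deg = c(NA, 0), magnitude_kmyr = c(0, 2.2))
  attr(tracks, "dt") <- 10
  rows <- build_comparison(tracks, vgrad = vg, dem = dem)
  expect_false(rows$grad_valid[1])
  expect_true(rows$grad_valid[2])
  expect_equal(rows$region, c("west", "west"))
  # uniform northward climate + linear slope: elevational velocity = slope * speed
  expect_equal(rows$grad_v_elev[2], 5 * rows$grad_v_lat[2], tolerance = 1e-6)
  # flat DEM gives zero climate elevational velocity
  rows_flat <- build_comparison(tracks, vgrad = vg, dem = make_dem("flat"))
  expect_equal(rows_flat$grad_v_elev[2], 0)
})

test_that("tracking-factor recovery through the full generator pathway", {
  grid_lat <- seq(30, 55, 1); grid_lon <- seq(-125, -90, 1)
  vn <- outer(rep(1, length(grid_lat)),
              1 + 1.5 * sin(2 * pi * (grid_lon + 125) / 35))
  fld <- velocity_field(matrix(0, length(grid_lat), length(grid_lon)), vn,
                        grid_lat, grid_lon, method = "prescribed", dt = 10)
  sc <- species_scenario(n_species = 60, tracking = 0.5, noise_sd = 5,
                         n_sites = 6, lat_range = c(38, 47),
                         lon_range = c(-120, -95), seed = 14)
  recs <- make_species_records(sc, fld, 1960:1979)
  tracks <- centroid_tracks(recs, c(1960, 1970), c(1970, 1980), mode = "birds")
  rows <- build_comparison(tracks, vgrad = fld)
  f <- component_fit(rows, "lat", "gradient")
  expect_lt(abs(f$slope - 0.5), 3 * f$se)
  expect_gt(f$r, 0.9)
})
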