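#' Wrapped heading difference
#'
#' Difference between two headings wrapped to `[-180, 180)` via
#' `(h_species - h_climate + 180) mod 360 - 180`. Undefined headings (`NA`,
#' from zero-magnitude vectors) propagate as `NA` rather than being imputed
#' as zero.
#'
#' @param h_species,h_climate headings in degrees (vectorized).
#' @return degrees in `[-180, 180)`.
#' @export
heading_difference <- function(h_species, h_climate) {
  (h_species - h_climate + 180) %% 360 - 180
}

#' Pair species tracks with climate velocities from both methods
#'
#' For every species track, the climate velocity it experienced is the
#' velocity-field value at the *initial* decadal centroid (nearest node).
#' The climate elevational velocity is obtained by displacing the initial
#' centroid along the climate vector for the full period offset and
#' differencing the DEM: `[DEM(c0 + v dt) - DEM(c0)] / dt`. Rows whose
#' climate node is masked invalid are flagged and excluded downstream.
#'
#' @param tracks a [centroid_tracks()] data.frame.
#' @param vgrad,vmatch [velocity_field()] objects from the gradient and MATCH
#'   estimators (either may be `NULL` to skip that method).
#' @param dem optional [dem_grid()]; without it climate elevational
#'   velocities are `NA`.
#' @param split_lon region-mask longitude: rows with initial centroid
#'   longitude <= `split_lon` are labelled `"west"`, others `"east"`.
#' @param elev_displacement `"full_dt"` (default; displacement over the whole
#'   period offset) or `"per_year"` (1-year displacement) when sampling the
#'   DEM along the climate vector.
#' @return A data.frame of class `comparison_rows`: species velocities,
#'   per-method climate velocities (`grad_*`, `match_*`), validity flags,
#'   heading differences and region labels.
#' @export
build_comparison <- function(tracks, vgrad = NULL, vmatch = NULL, dem = NULL,
                             split_lon = -100,
                             elev_displacement = c("full_dt", "per_year")) {
  elev_displacement <- match.arg(elev_displacement)
  dt <- attr(tracks, "dt")
  if (is.null(dt)) stop("tracks must carry a dt attribute (see centroid_tracks)")
  n <- nrow(tracks)
  out <- data.frame(
    species_id = tracks$species_id,
    pair = paste(tracks$decade0, tracks$decade1, sep = " to "),
    region = ifelse(tracks$lon0 <= split_lon, "west", "east"),
    sp_v_lon = tracks$v_lon_kmyr, sp_v_lat = tracks$v_lat_kmyr,
    sp_v_elev = tracks$v_elev_myr, sp_heading = tracks$heading_deg,
    stringsAsFactors = FALSE)
  for (m in c("grad", "match")) {
    v <- if (m == "grad") vgrad else vmatch
    if (is.null(v)) next
    vv <- velocity_at(v, tracks$lat0, tracks$lon0)
    helev <- rep(NA_real_, n)
    if (!is.null(dem) && n > 0) {
      step <- if (elev_displacement == "full_dt") dt else 1
      e0 <- sample_elevation(dem, tracks$lat0, tracks$lon0)
      lat_d <- tracks$lat0 + vv$north * step / KM_PER_DEG
      lon_d <- tracks$lon0 + vv$east * step /
        km_per_deg_lon((tracks$lat0 + lat_d) / 2)
      e1 <- sample_elevation(dem, lat_d, lon_d)
      helev <- (e1 - e0) / step
    }
    hc <- heading_of(vv$east, vv$north)
    out[[paste0(m, "_v_lon")]] <- vv$east
    out[[paste0(m, "_v_lat")]] <- vv$north
    out[[paste0(m, "_v_elev")]] <- helev
    out[[paste0(m, "_valid")]] <- vv$valid
    out[[paste0(m, "_heading_diff")]] <-
      heading_difference(tracks$heading_deg, hc)
  }
  attr(out, "dt") <- dt
  class(out) <- c("comparison_rows", "data.frame")
  out
}

.method_prefix <- function(method) {
  switch(match.arg(method, c("gradient", "match")), gradient = "grad",
         match = "match")
}

.fit_xy <- function(rows, component, method) {
  component <- match.arg(component, c("lon", "lat", "elev"))
  p <- .method_prefix(method)
  x <- rows[[paste0(p, "_v_", component)]]
  y <- rows[[paste0("sp_v_", component)]]
  if (is.null(x)) stop("no climate velocities for method ", method)
  ok <- rows[[paste0(p, "_valid")]] & is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], component = component)
}

#' Per-component linear fit of species velocity on climate velocity
#'
#' Ordinary least squares of the species-shift velocity component on the
#' climate-velocity component from one method, after removing outliers whose
#' climate or species component exceeds `outlier_threshold` in absolute
#' value (horizontal components only by default; elevational components are
#' in m/yr, so their threshold is a separate optional argument). Reports the
#' slope, its standard error, Pearson r and the two-sided p-value.
#'
#' @param rows a [build_comparison()] data.frame.
#' @param component `"lon"`, `"lat"` or `"elev"`.
#' @param method `"gradient"` or `"match"`.
#' @param outlier_threshold absolute-value cut in km/yr for the horizontal
#'   components (default 1000).
#' @param elev_threshold optional cut in m/yr for the elevational component
#'   (default `NULL` = no cut).
#' @param intercept include an intercept (default `TRUE`).
#' @return An object of class `component_fit` with elements `slope`, `se`,
#'   `r`, `p`, `n_used`, `n_removed` and the underlying `lm` fit.
#' @export
component_fit <- function(rows, component = c("lon", "lat", "elev"),
                          method = c("gradient", "match"),
                          outlier_threshold = 1000, elev_threshold = NULL,
                          intercept = TRUE) {
  component <- match.arg(component)
  d <- .fit_xy(rows, component, method)
  thr <- if (component == "elev") elev_threshold else outlier_threshold
  n_in <- length(d$x)
  if (!is.null(thr)) {
    keep <- abs(d$x) <= thr & abs(d$y) <= thr
  } else keep <- rep(TRUE, n_in)
  x <- d$x[keep]; y <- d$y[keep]
  if (length(x) < 3) stop("fewer than 3 points after outlier removal")
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  ct <- stats::cor.test(x, y)
  structure(list(slope = slope, se = se, r = unname(ct$estimate),
                 p = ct$p.value, n_used = length(x),
                 n_removed = n_in - length(x), component = component,
                 method = match.arg(method), intercept = intercept,
                 fit = fit),
            class = "component_fit")
}

#' @export
print.component_fit <- function(x, ...) {
  cat(sprintf("component_fit [%s, %s]: slope %.4f +/- %.4f, r = %.3f, p = %.3g (n = %d, %d outliers removed)\n",
              x$method, x$component, x$slope, x$se, x$r, x$p, x$n_used,
              x$n_removed))
  invisible(x)
}

#' @export
coef.component_fit <- function(object, ...) stats::coef(object$fit)

#' @export
summary.component_fit <- function(object, ...) summary(object$fit)

#' Linear mixed model of species velocity on climate velocity
#'
#' When rows from several decade pairs are aggregated, the same species
#' contributes repeatedly; a linear mixed model with a random intercept per
#' species accounts for that. Fitted by maximum likelihood; the fixed-slope
#' z value is estimate / SE with a normal-approximation two-sided p-value.
#' Singular fits (e.g. zero between-species variance) are flagged, not
#' raised.
#'
#' @inheritParams component_fit
#' @return An object of class `mixed_fit`: `estimate`, `se`, `z`, `p`,
#'   `ranef_var`, `n_obs`, `n_groups`, `singular`, and the `lmer` fit.
#' @export
mixed_fit <- function(rows, component = c("lon", "lat", "elev"),
                      method = c("gradient", "match"),
                      outlier_threshold = 1000, elev_threshold = NULL) {
  component <- match.arg(component)
  p <- .method_prefix(method)
  x <- rows[[paste0(p, "_v_", component)]]
  y <- rows[[paste0("sp_v_", component)]]
  ok <- rows[[paste0(p, "_valid")]] & is.finite(x) & is.finite(y)
  thr <- if (component == "elev") elev_threshold else outlier_threshold
  if (!is.null(thr)) ok <- ok & abs(x) <= thr & abs(y) <= thr
  d <- data.frame(x = x[ok], y = y[ok], species = rows$species_id[ok])
  if (length(unique(d$species)) < 2) stop("need >= 2 species")
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.rankZ = "ignore")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | species), data = d, REML = FALSE,
               control = ctrl)))
  co <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                 error = function(e) NULL)
  if (!is.null(co) && is.finite(co["x", "Std. Error"])) {
    est <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  } else {
    # fully degenerate fit (e.g. zero residual variance): keep the ML
    # fixed-effect estimate, take the SE from the OLS limit
    est <- unname(lme4::fixef(fit)["x"])
    se <- suppressWarnings(
      summary(stats::lm(y ~ x, data = d))$coefficients["x", "Std. Error"])
  }
  z <- est / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(estimate = est, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 ranef_var = vc$vcov[vc$grp == "species"],
                 n_obs = nrow(d), n_groups = length(unique(d$species)),
                 singular = lme4::isSingular(fit),
                 component = component, method = match.arg(method),
                 fit = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("mixed_fit [%s, %s]: slope %.4f +/- %.4f, z = %.2f, p = %.3g (%d obs, %d species%s)\n",
              x$method, x$component, x$estimate, x$se, x$z, x$p, x$n_obs,
              x$n_groups, if (x$singular) ", singular fit" else ""))
  invisible(x)
}

#' @export
coef.mixed_fit <- function(object, ...) lme4::fixef(object$fit)

#' Multilinear fit of each species component on all climate components
#'
#' Sensitivity check for crossed-axis influence: each species velocity
#' component is regressed jointly on the latitudinal, longitudinal and
#' elevational climate velocities of one method. Rank-deficient designs
#' (collinear regressors) are flagged.
#'
#' @inheritParams component_fit
#' @param response species component to regress (`"lon"`, `"lat"`, `"elev"`).
#' @return An object of class `multilinear_fit` with a coefficient table
#'   (`estimate`, `se`, `p` per regressor) and a `rank_deficient` flag.
#' @export
multilinear_fit <- function(rows, response = c("lon", "lat", "elev"),
                            method = c("gradient", "match")) {
  response <- match.arg(response)
  p <- .method_prefix(method)
  d <- data.frame(y = rows[[paste0("sp_v_", response)]],
                  v_lon = rows[[paste0(p, "_v_lon")]],
                  v_lat = rows[[paste0(p, "_v_lat")]],
                  v_elev = rows[[paste0(p, "_v_elev")]])
  d <- d[rows[[paste0(p, "_valid")]] & stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 5) stop("fewer than 5 valid rows")
  X <- stats::model.matrix(~ v_lon + v_lat + v_elev, d)
  rank_def <- qr(X)$rank < ncol(X)
  fit <- stats::lm(y ~ v_lon + v_lat + v_elev, data = d)
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, rank_deficient = rank_def,
                 response = response, method = match.arg(method),
                 n = nrow(d), fit = fit),
            class = "multilinear_fit")
}

#' @export
print.multilinear_fit <- function(x, ...) {
  cat(sprintf("multilinear_fit [%s, species %s on all climate components], n = %d%s\n",
              x$method, x$response, x$n,
              if (x$rank_deficient) " (rank deficient)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Circular summary of heading differences
#'
#' Circular mean and standard deviation of the species-minus-climate heading
#' differences via the resultant vector, plus histogram counts over
#' `[-180, 180)`. Rows with an undefined heading (zero-magnitude velocity)
#' are excluded, not imputed.
#'
#' @inheritParams component_fit
#' @param bins number of histogram bins spanning `[-180, 180)`.
#' @return A list with `mean` (degrees, `NA` when the resultant vanishes),
#'   `sd` (degrees), `resultant` (mean resultant length), `n`, `breaks` and
#'   `counts`.
#' @export
heading_summary <- function(rows, method = c("gradient", "match"), bins = 36) {
  p <- .method_prefix(method)
  d <- rows[[paste0(p, "_heading_diff")]]
  d <- d[rows[[paste0(p, "_valid")]] & is.finite(d)]
  if (!length(d)) stop("no defined heading differences")
  th <- .deg2rad(d)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mu <- if (R < 1e-12) NA_real_ else .rad2deg(atan2(S, C))
  sd <- if (R < 1e-12) NA_real_ else .rad2deg(sqrt(-2 * log(R)))
  breaks <- seq(-180, 180, length.out = bins + 1)
  counts <- as.integer(table(cut(d, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  list(mean = mu, sd = sd, resultant = R, n = length(d),
       breaks = breaks, counts = counts)
}
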