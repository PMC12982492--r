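#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: synthetic scenario specs (or
#' paths to CSV inputs in the same schemas), decade windows, mode, methods,
#' estimator settings and the master seed. The master seed fans out to fixed
#' per-stage child seeds so stages are individually reproducible.
#'
#' @param field_scenario a [field_scenario()], or a path to a yearly field
#'   series CSV (see [write_field_series_csv()]).
#' @param species_scenario a [species_scenario()], or a path to a records CSV.
#' @param dem a [dem_grid()], `NULL` (skip elevation analysis), or a path to
#'   a DEM CSV.
#' @param decades list of half-open year windows in increasing order, e.g.
#'   `list(c(1950, 1960), c(1960, 1970))`.
#' @param mode `"birds"` or `"marine"`.
#' @param methods character subset of `c("gradient", "match")`.
#' @param min_grad gradient-method blow-up guard (degC/km).
#' @param match_config a [match_config()]; its seed is overridden by the
#'   derived stage seed.
#' @param outlier_threshold km/yr cut for the per-component fits.
#' @param split_lon region-split longitude (default -100).
#' @param first_to_last also analyse the first-to-last decade pair when more
#'   than two decades are given (default `TRUE`).
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(field_scenario, species_scenario, dem = NULL,
                       decades, mode = c("birds", "marine"),
                       methods = c("gradient", "match"), min_grad = 1e-4,
                       match_config = velomatch::match_config(),
                       outlier_threshold = 1000, split_lon = -100,
                       first_to_last = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(field_scenario = field_scenario,
                 species_scenario = species_scenario, dem = dem,
                 decades = decades, mode = mode, methods = methods,
                 min_grad = min_grad, match_config = match_config,
                 outlier_threshold = outlier_threshold,
                 split_lon = split_lon, first_to_last = first_to_last,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the schema without running anything and returns a character vector
#' of violations (empty when the configuration is valid).
#'
#' @param config a [run_config()] (or a bare list with the same fields).
#' @return character vector of violation messages.
#' @export
validate_run_config <- function(config) {
  v <- character()
  d <- config$decades
  if (is.null(d) || length(d) < 2) {
    v <- c(v, "at least two decade windows required")
  } else {
    for (w in d)
      if (length(w) != 2 || w[2] <= w[1])
        v <- c(v, sprintf("window [%s] is not a valid half-open interval",
                          paste(w, collapse = ", ")))
    if (length(v) == 0) {
      starts <- vapply(d, `[`, 0, 1)
      ends <- vapply(d, `[`, 0, 2)
      if (any(diff(starts) <= 0))
        v <- c(v, "decade windows must be in increasing order")
      if (any(starts[-1] < ends[-length(ends)]))
        v <- c(v, "decade windows must not overlap")
    }
  }
  if (is.null(config$methods) || !length(config$methods) ||
      !all(config$methods %in% c("gradient", "match")))
    v <- c(v, "methods must be a non-empty subset of gradient, match")
  if (!is.null(config$mode) && !config$mode %in% c("birds", "marine"))
    v <- c(v, "mode must be birds or marine")
  if (!is.null(config$min_grad) && config$min_grad <= 0)
    v <- c(v, "min_grad must be positive")
  if (is.null(config$field_scenario))
    v <- c(v, "field_scenario (scenario or CSV path) required")
  if (is.null(config$species_scenario))
    v <- c(v, "species_scenario (scenario or CSV path) required")
  v
}

# fixed fan-out of the master seed into per-stage seeds (kept below 2^31)
.stage_seed <- function(master, stage) {
  (as.integer(master) * 1009L + as.integer(stage) * 9973L) %% 2147483647L
}

#' Run the full pipeline
#'
#' Simulates (or loads) climate fields, species records and DEM; computes
#' decadal means, both velocity fields for every decade pair, applies the
#' mode's inclusion filter, builds centroid tracks and comparison rows, fits
#' the per-component statistics per pair plus mixed models over aggregated
#' pairs, and writes everything under `out_dir` together with a JSON
#' manifest. Deterministic for a fixed master seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (Invisibly) a list with the in-memory results: `velocities`,
#'   `tracks`, `comparison`, `fits`, `mixed`, `headings`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  viol <- validate_run_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  series <- if (is.character(config$field_scenario))
    read_field_series_csv(config$field_scenario)
  else make_temperature_series(config$field_scenario)
  dem <- if (is.character(config$dem)) read_field_csv(config$dem) else config$dem

  decades <- config$decades
  pairs <- lapply(seq_len(length(decades) - 1),
                  function(i) list(d0 = decades[[i]], d1 = decades[[i + 1]]))
  if (isTRUE(config$first_to_last) && length(decades) > 2)
    pairs <- c(pairs, list(list(d0 = decades[[1]],
                                d1 = decades[[length(decades)]],
                                label = "first-to-last")))

  means <- lapply(decades, function(w) decadal_mean(series, w))

  # --- velocity fields per pair -------------------------------------------
  velocities <- list()
  for (k in seq_along(pairs)) {
    d0 <- pairs[[k]]$d0; d1 <- pairs[[k]]$d1
    f0 <- means[[which(vapply(decades, function(w) all(w == d0), TRUE))[1]]]
    f1 <- means[[which(vapply(decades, function(w) all(w == d1), TRUE))[1]]]
    lab <- sprintf("%g-%g_to_%g-%g", d0[1], d0[2], d1[1], d1[2])
    vs <- list()
    if ("gradient" %in% config$methods)
      vs$gradient <- gradient_velocity(f0, f1, min_grad = config$min_grad)
    if ("match" %in% config$methods) {
      mc <- config$match_config
      mc$seed <- .stage_seed(config$seed, 100L + k)
      vs$match <- match_velocity(f0, f1, config = mc)
    }
    velocities[[lab]] <- vs
    for (m in names(vs))
      write_velocity_csv(vs[[m]], file.path(out_dir,
                                            sprintf("velocity_%s_%s.csv", m, lab)))
  }

  # --- species records ----------------------------------------------------
  if (is.character(config$species_scenario)) {
    records <- read_records_csv(config$species_scenario)
  } else {
    sc <- config$species_scenario
    sc$seed <- .stage_seed(config$seed, 2L)
    adv <- velocities[[1]]
    adv <- if ("match" %in% names(adv)) adv$match else adv$gradient
    years <- seq(min(vapply(decades, `[`, 0, 1)),
                 max(vapply(decades, `[`, 0, 2)) - 1)
    records <- make_species_records(sc, adv, years)
  }
  write_records_csv(records, file.path(out_dir, "records.csv"))

  # --- per-pair tracks, comparison, fits ----------------------------------
  filt <- if (config$mode == "birds") filter_birds else filter_marine
  fits <- list(); tracks_all <- list(); comp_all <- list(); headings <- list()
  for (k in seq_along(pairs)) {
    d0 <- pairs[[k]]$d0; d1 <- pairs[[k]]$d1
    lab <- sprintf("%g-%g_to_%g-%g", d0[1], d0[2], d1[1], d1[2])
    kept <- filt(records, d0, d1)
    if (!nrow(kept)) next
    tr <- centroid_tracks(kept, d0, d1, mode = config$mode, dem = dem)
    vs <- velocities[[lab]]
    cmp <- build_comparison(tr, vgrad = vs$gradient, vmatch = vs$match,
                            dem = dem, split_lon = config$split_lon)
    tracks_all[[lab]] <- tr
    comp_all[[lab]] <- cmp
    write_tracks_csv(tr, file.path(out_dir, sprintf("tracks_%s.csv", lab)))
    for (m in intersect(c("gradient", "match"), config$methods)) {
      comps <- c("lon", "lat", if (!is.null(dem)) "elev")
      for (cc in comps) {
        f <- tryCatch(component_fit(cmp, cc, m,
                                    outlier_threshold = config$outlier_threshold),
                      error = function(e) NULL)
        if (!is.null(f))
          fits[[length(fits) + 1]] <- data.frame(
            pair = lab, method = m, component = cc, slope = f$slope,
            se = f$se, r = f$r, p = f$p, n = f$n_used,
            n_removed = f$n_removed, stringsAsFactors = FALSE)
      }
      h <- tryCatch(heading_summary(cmp, m), error = function(e) NULL)
      if (!is.null(h))
        headings[[length(headings) + 1]] <- data.frame(
          pair = lab, method = m, mean = h$mean, sd = h$sd, n = h$n,
          stringsAsFactors = FALSE)
    }
  }
  fits_df <- if (length(fits)) do.call(rbind, fits) else NULL
  if (!is.null(fits_df))
    utils::write.csv(fits_df, file.path(out_dir, "fits.csv"), row.names = FALSE)
  head_df <- if (length(headings)) do.call(rbind, headings) else NULL
  if (!is.null(head_df))
    utils::write.csv(head_df, file.path(out_dir, "headings.csv"),
                     row.names = FALSE)

  # --- aggregated mixed models --------------------------------------------
  mixed <- list()
  ftl <- vapply(pairs, function(p) identical(p$label, "first-to-last"), TRUE)
  consecutive_labs <- vapply(pairs[!ftl], function(p)
    sprintf("%g-%g_to_%g-%g", p$d0[1], p$d0[2], p$d1[1], p$d1[2]), "")
  agg <- do.call(rbind, comp_all[intersect(consecutive_labs, names(comp_all))])
  mixed_rows <- list()
  if (!is.null(agg) && nrow(agg)) {
    for (m in intersect(c("gradient", "match"), config$methods)) {
      comps <- c("lon", "lat", if (!is.null(dem)) "elev")
      for (cc in comps) {
        f <- tryCatch(mixed_fit(agg, cc, m,
                                outlier_threshold = config$outlier_threshold),
                      error = function(e) NULL)
        if (!is.null(f)) {
          mixed[[paste(m, cc, sep = "_")]] <- f
          mixed_rows[[length(mixed_rows) + 1]] <- data.frame(
            method = m, component = cc, estimate = f$estimate, se = f$se,
            z = f$z, p = f$p, n_obs = f$n_obs, n_groups = f$n_groups,
            singular = f$singular, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(mixed_rows))
    utils::write.csv(do.call(rbind, mixed_rows),
                     file.path(out_dir, "mixed.csv"), row.names = FALSE)

  manifest <- list(
    package = "velomatch",
    version = as.character(utils::packageVersion("velomatch")),
    seed = config$seed, mode = config$mode, methods = config$methods,
    decades = decades, min_grad = config$min_grad,
    outlier_threshold = config$outlier_threshold,
    split_lon = config$split_lon,
    n_records = nrow(records),
    pairs = names(velocities))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(velocities = velocities, tracks = tracks_all,
                 comparison = comp_all, fits = fits_df, mixed = mixed,
                 headings = head_df, manifest = manifest))
}
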