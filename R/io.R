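# Plain-text (CSV) serialization of the package's containers. Metadata rides
# in leading comment lines ("# key: value") so a file round-trips to the same
# object; records and track tables are standard headered CSV.

.write_meta_csv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

.read_meta <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- strsplit(trimws(sub("^[^:]*:", "", kv)), " +")[[1]]
  }
  meta
}

#' Write / read a gridded field as CSV
#'
#' Long format `lat,lon,value` with the period window and units in comment
#' headers.
#'
#' @param f a [gridded_field()].
#' @param path file path.
#' @return `read_field_csv` returns a [gridded_field()].
#' @export
write_field_csv <- function(f, path) {
  stopifnot(inherits(f, "gridded_field") || inherits(f, "dem_grid"))
  g <- expand.grid(lat = f$lat, lon = f$lon)
  meta <- list(type = class(f)[1], units = f$units)
  if (!is.null(f$period)) meta$period <- f$period
  .write_meta_csv(data.frame(lat = g$lat, lon = g$lon, value = as.vector(f$values)),
                  path, meta)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  meta <- .read_meta(path)
  d <- utils::read.csv(path, comment.char = "#")
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  v <- matrix(NA_real_, length(lat), length(lon))
  v[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$value
  period <- if (!is.null(meta$period)) as.numeric(meta$period) else NULL
  units <- if (!is.null(meta$units)) meta$units else "degC"
  if (identical(meta$type, "dem_grid")) dem_grid(v, lat, lon)
  else gridded_field(v, lat, lon, period = period, units = units)
}

#' Write / read a yearly field series as CSV
#'
#' Long format `year,lat,lon,value`.
#'
#' @param series a `field_series` (named list of [gridded_field()]).
#' @param path file path.
#' @export
write_field_series_csv <- function(series, path) {
  parts <- lapply(names(series), function(y) {
    f <- series[[y]]
    g <- expand.grid(lat = f$lat, lon = f$lon)
    data.frame(year = as.integer(y), lat = g$lat, lon = g$lon,
               value = as.vector(f$values))
  })
  .write_meta_csv(do.call(rbind, parts), path,
                  list(type = "field_series", units = series[[1]]$units))
  invisible(path)
}

#' @rdname write_field_series_csv
#' @export
read_field_series_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  years <- sort(unique(d$year))
  out <- lapply(years, function(y) {
    dy <- d[d$year == y, , drop = FALSE]
    lat <- sort(unique(dy$lat)); lon <- sort(unique(dy$lon))
    v <- matrix(NA_real_, length(lat), length(lon))
    v[cbind(match(dy$lat, lat), match(dy$lon, lon))] <- dy$value
    gridded_field(v, lat, lon, period = y)
  })
  names(out) <- years
  class(out) <- c("field_series", "list")
  out
}

#' Write / read a velocity field as CSV
#'
#' Long format `lat,lon,v_east,v_north,valid` (km/yr, valid 0/1) with method
#' and dt in comment headers.
#'
#' @param v a [velocity_field()].
#' @param path file path.
#' @export
write_velocity_csv <- function(v, path) {
  stopifnot(inherits(v, "velocity_field"))
  g <- expand.grid(lat = v$lat, lon = v$lon)
  .write_meta_csv(data.frame(lat = g$lat, lon = g$lon,
                             v_east = as.vector(v$v_east),
                             v_north = as.vector(v$v_north),
                             valid = as.integer(as.vector(v$valid))),
                  path, list(type = "velocity_field", method = v$method,
                             dt = v$dt))
  invisible(path)
}

#' @rdname write_velocity_csv
#' @export
read_velocity_csv <- function(path) {
  meta <- .read_meta(path)
  d <- utils::read.csv(path, comment.char = "#")
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  idx <- cbind(match(d$lat, lat), match(d$lon, lon))
  ve <- vn <- matrix(NA_real_, length(lat), length(lon))
  ok <- matrix(TRUE, length(lat), length(lon))
  ve[idx] <- d$v_east; vn[idx] <- d$v_north; ok[idx] <- d$valid == 1
  velocity_field(ve, vn, lat, lon, valid = ok,
                 method = meta$method, dt = as.numeric(meta$dt))
}

#' Write / read observation records as CSV
#'
#' Schema `species_id,site_id,year,lat,lon,count,presence` (count empty in
#' marine mode, presence 0/1).
#'
#' @param records observation-record data.frame.
#' @param path file path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records[, c("species_id", "site_id", "year", "lat", "lon",
                               "count", "presence")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, colClasses = c(species_id = "character",
                                       site_id = "character"))
}

#' Write centroid tracks as CSV
#' @param tracks a [centroid_tracks()] data.frame.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  .write_meta_csv(as.data.frame(tracks), path,
                  list(type = "centroid_tracks", dt = attr(tracks, "dt")))
  invisible(path)
}
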