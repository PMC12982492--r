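#' Inclusion filter for count (bird-survey) records
#'
#' Applies the two inclusion criteria used for volunteer winter bird counts:
#'
#' * a species is kept only if it was reported at least 5 times in *each*
#'   year of both the initial and final decade;
#' * an observation spot is kept for a species only if that species was
#'   observed there every year of both decades, with at least 2 observations
#'   per year (limits the impact of identification errors).
#'
#' Failing sites are dropped first; the species-level rule is then evaluated,
#' by default on the surviving (post-site-filter) records. Whether the
#' species rule instead uses the original (pre-site-filter) counts is
#' configurable, as both readings of the criteria are defensible.
#'
#' @param records data.frame with columns `species_id`, `site_id`, `year`.
#' @param decade0,decade1 disjoint half-open year windows.
#' @param species_counts `"post_site"` (default) or `"pre_site"`: which
#'   record set the >= 5 reports/year species rule is evaluated on.
#' @return The subset of `records` belonging to surviving (species, site)
#'   pairs (all years retained).
#' @export
filter_birds <- function(records, decade0, decade1,
                         species_counts = c("post_site", "pre_site")) {
  species_counts <- match.arg(species_counts)
  yrs <- .filter_years(decade0, decade1)
  r <- records[records$year %in% yrs, , drop = FALSE]

  # site rule: (species, site) observed >= 2 times in every required year
  key <- paste(r$species_id, r$site_id, sep = "\r")
  cnt <- table(key, factor(r$year, levels = yrs))
  good_pairs <- rownames(cnt)[apply(cnt >= 2, 1, all)]
  keep_pair <- key %in% good_pairs

  # species rule: >= 5 reports in every required year
  base <- if (species_counts == "post_site") r[keep_pair, , drop = FALSE] else r
  scnt <- table(base$species_id, factor(base$year, levels = yrs))
  good_sp <- rownames(scnt)[apply(scnt >= 5, 1, all)]

  ok_pair <- paste(records$species_id, records$site_id, sep = "\r") %in% good_pairs
  records[ok_pair & records$species_id %in% good_sp, , drop = FALSE]
}

#' Inclusion filter for presence (trawl-survey) records
#'
#' Automated presence-absence surveys define no observation spots, so the
#' site rule is replaced by the requirement that a species be observed at
#' least 3 times in every year of both decades.
#'
#' @inheritParams filter_birds
#' @return The subset of `records` belonging to surviving species.
#' @export
filter_marine <- function(records, decade0, decade1) {
  yrs <- .filter_years(decade0, decade1)
  r <- records[records$year %in% yrs, , drop = FALSE]
  scnt <- table(r$species_id, factor(r$year, levels = yrs))
  good_sp <- rownames(scnt)[apply(scnt >= 3, 1, all)]
  records[records$species_id %in% good_sp, , drop = FALSE]
}

.filter_years <- function(decade0, decade1) {
  if (max(decade0[1], decade1[1]) < min(decade0[2], decade1[2]))
    stop("decades must be disjoint")
  c(seq(decade0[1], decade0[2] - 1), seq(decade1[1], decade1[2] - 1))
}
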