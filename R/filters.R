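#' Filtering configuration for banding-recovery records
#'
#' The banding-program code sets are versioned and external, so the sets
#' that define "banded as nestling/fledgling", "found dead" and acceptable
#' coordinate precision are configuration, not constants. Defaults use the
#' plain labels emitted by [simulate_banding_records()].
#'
#' @param natal_age_codes Age-at-banding codes accepted as natal (banded in
#'   the nest or shortly after fledging).
#' @param dead_condition_codes Recovery-condition codes accepted as
#'   "found dead" (excludes recoveries at banding stations or hunting
#'   sites, which are spatially biased by human activity).
#' @param max_precision_code Largest acceptable coordinate-precision class,
#'   on an ordinal scale where 1 = 1-arc-minute block and 10 =
#'   10-arc-minute block. Records coarser than the 1-minute block are
#'   discarded by default.
#' @param maturity_years Minimum elapsed time (years) between banding and
#'   recovery for the bird to count as a mature adult at recovery.
#'   Default 1.
#'
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(natal_age_codes = c("nestling", "fledgling"),
                          dead_condition_codes = "found_dead",
                          max_precision_code = 1,
                          maturity_years = 1) {
  stopifnot(length(natal_age_codes) >= 1, length(dead_condition_codes) >= 1,
            is.numeric(max_precision_code), is.numeric(maturity_years))
  structure(list(natal_age_codes = natal_age_codes,
                 dead_condition_codes = dead_condition_codes,
                 max_precision_code = max_precision_code,
                 maturity_years = maturity_years),
            class = "filter_config")
}

#' Is a date inside a species' breeding season?
#'
#' Breeding seasons are month bounds (earliest and latest month reported);
#' the test uses the calendar month only. Wrap-around seasons (e.g.
#' November to February) are supported.
#'
#' @param dates A `Date` vector (or anything `as.Date()` accepts).
#' @param start_month,end_month Integer months 1-12 bounding the season.
#' @return Logical vector.
#' @export
#' @examples
#' in_breeding_season(as.Date("2001-06-15"), 4, 8)   # TRUE
#' in_breeding_season(as.Date("2001-03-15"), 11, 2)  # FALSE
in_breeding_season <- function(dates, start_month, end_month) {
  stopifnot(all(start_month %in% 1:12), all(end_month %in% 1:12))
  m <- as.integer(format(as.Date(dates), "%m"))
  ifelse(start_month <= end_month,
         m >= start_month & m <= end_month,
         m >= start_month | m <= end_month)
}

#' Is a point inside a species' breeding-range bounding box?
#'
#' Range limits are the most extreme points of the species' breeding
#' distribution. The longitudinal interval runs eastward from `lon_min` to
#' `lon_max`, so boxes that straddle the antimeridian (`lon_min > lon_max`)
#' are handled.
#'
#' @param lat,lon Point coordinates, decimal degrees.
#' @param lat_min,lat_max Latitude bounds, `lat_min <= lat_max`.
#' @param lon_min,lon_max Longitude bounds of the eastward interval.
#' @return Logical vector.
#' @export
#' @examples
#' in_breeding_bbox(50, -100, 40, 60, -120, -80)  # TRUE
#' in_breeding_bbox(55, 175, 50, 60, 170, -170)   # TRUE (antimeridian box)
in_breeding_bbox <- function(lat, lon, lat_min, lat_max, lon_min, lon_max) {
  if (any(lat_min > lat_max)) {
    stop("degenerate bbox: lat_min > lat_max", call. = FALSE)
  }
  if (any(lat_min == lat_max) || any(lon_min == lon_max)) {
    stop("degenerate bbox: zero width", call. = FALSE)
  }
  lon <- normalize_lon(lon)
  lon_min <- normalize_lon(lon_min)
  lon_max <- normalize_lon(lon_max)
  in_lat <- lat >= lat_min & lat <= lat_max
  in_lon <- ifelse(lon_min <= lon_max,
                   lon >= lon_min & lon <= lon_max,
                   lon >= lon_min | lon <= lon_max)
  in_lat & in_lon
}

# The fixed application order of the record filters; audit attribution
# follows this order (a record failing several filters is attributed to
# the first).
filter_names <- function() {
  c("natal_age", "maturity", "breeding_season", "breeding_range",
    "found_dead", "precision")
}

elapsed_years <- function(band_date, rec_date) {
  as.numeric(as.Date(rec_date) - as.Date(band_date)) / 365.25
}

filter_fail_matrix <- function(records, meta, config) {
  ey <- elapsed_years(records$band_date, records$rec_date)
  cbind(
    natal_age = !(records$age_code %in% config$natal_age_codes),
    maturity = ey < config$maturity_years,
    breeding_season =
      !(in_breeding_season(records$band_date, meta$season_start_month,
                           meta$season_end_month) &
        in_breeding_season(records$rec_date, meta$season_start_month,
                           meta$season_end_month)),
    breeding_range =
      !(in_breeding_bbox(records$band_lat, records$band_lon, meta$lat_min,
                         meta$lat_max, meta$lon_min, meta$lon_max) &
        in_breeding_bbox(records$rec_lat, records$rec_lon, meta$lat_min,
                         meta$lat_max, meta$lon_min, meta$lon_max)),
    found_dead = !(records$rec_condition %in% config$dead_condition_codes),
    precision = records$precision_code > config$max_precision_code
  )
}

#' Filter banding-recovery records for natal-dispersal estimation
#'
#' Applies, in a fixed documented order, the record filters that make a
#' banding-to-recovery pair interpretable as a natal dispersal event:
#' banded as nestling/fledgling (natal site), recovered as a mature adult
#' (potential breeding site), banded and recovered during the breeding
#' season and within the breeding range (excludes migratory movements),
#' found dead (excludes recoveries at banding stations and hunting sites),
#' and coordinate precision no coarser than a 1-arc-minute block.
#'
#' @param records A data frame with one row per banding-recovery pair;
#'   required columns: `band_id`, `species`, `band_date`, `band_lat`,
#'   `band_lon`, `age_code`, `rec_date`, `rec_lat`, `rec_lon`,
#'   `rec_condition`, `precision_code`. Dates ISO-8601, coordinates
#'   decimal degrees.
#' @param meta Per-species metadata with columns `species`,
#'   `season_start_month`, `season_end_month`, `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`.
#' @param config A [filter_config()].
#' @param order Character vector permuting [filter_names()]; changes only
#'   audit attribution, never the retained set.
#'
#' @return The retained records as a tibble, with the audit attached as
#'   attribute `"audit"` (retrieve with [filter_audit()]): a tibble of
#'   per-filter removal counts, in application order, plus the final
#'   retained count; counts always sum to the input count.
#' @export
filter_records <- function(records, meta, config = filter_config(),
                           order = filter_names()) {
  records <- tibble::as_tibble(records)
  need <- c("band_id", "species", "band_date", "band_lat", "band_lon",
            "age_code", "rec_date", "rec_lat", "rec_lon", "rec_condition",
            "precision_code")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!setequal(order, filter_names())) {
    stop("`order` must be a permutation of filter_names()", call. = FALSE)
  }
  unknown <- setdiff(unique(records$species), meta$species)
  if (length(unknown)) {
    stop("species absent from metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    audit <- tibble::tibble(filter = order, removed = 0L)
    attr(records, "audit") <- list(removed = audit, retained = 0L, input = 0L)
    return(records)
  }
  m <- meta[match(records$species, meta$species), , drop = FALSE]
  fails <- filter_fail_matrix(records, m, config)[, order, drop = FALSE]
  # attribute each removed record to the first failed filter in `order`
  first_fail <- apply(fails, 1, function(z) if (any(z)) which(z)[1] else 0L)
  removed <- vapply(seq_along(order),
                    function(k) sum(first_fail == k), integer(1))
  keep <- first_fail == 0L
  out <- records[keep, , drop = FALSE]
  attr(out, "audit") <- list(
    removed = tibble::tibble(filter = order, removed = removed),
    retained = sum(keep),
    input = nrow(records)
  )
  out
}

#' Retrieve the filter audit attached to filtered records
#'
#' @param x The tibble returned by [filter_records()].
#' @return A list with `removed` (per-filter counts, application order),
#'   `retained` and `input`.
#' @export
filter_audit <- function(x) {
  a <- attr(x, "audit")
  if (is.null(a)) stop("no audit attached; was this produced by filter_records()?",
                       call. = FALSE)
  a
}
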