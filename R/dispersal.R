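#' Per-species natal dispersal distance estimates
#'
#' Computes the Vincenty distance between banding and recovery points for
#' each retained record and summarizes per species as the geometric mean
#' distance, the standard error of log distance, and the mean number of
#' years elapsed between banding and recovery (a covariate controlling for
#' breeding-dispersal contamination of natal estimates).
#'
#' Records with identical banding and recovery coordinates would give a
#' log of zero distance; distances are floored at half the 1-arc-minute
#' block resolution (~0.93 km) before logging, respecting the coordinate
#' resolution of the source data. The number of floored records is
#' reported per species.
#'
#' @param records Filtered records (see [filter_records()]); grouping is
#'   by the `species` column.
#' @param floor_km Minimum distance in km substituted before the log
#'   transform; default half a 1-arc-minute meridian block,
#'   `0.5 * 1.853` km.
#' @param ellipsoid Reference ellipsoid for [vincenty_km()].
#'
#' @return A tibble with one row per species: `species`, `n` (record
#'   count), `geomean_km` (geometric mean distance, `exp(mean(log d))`),
#'   `log_se` (`sd(log d)/sqrt(n)`, `NA` when n = 1),
#'   `mean_recovery_years`, `n_floored`. The geometric mean never exceeds
#'   the arithmetic mean of the same distances.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   band_id = c("a", "b", "c"), species = "sp1",
#'   band_date = as.Date("2001-06-01"), band_lat = 45, band_lon = -75,
#'   rec_date = as.Date("2003-06-01"),
#'   rec_lat = c(45.1, 45.5, 46), rec_lon = -75)
#' estimate_dispersal(rec)
estimate_dispersal <- function(records, floor_km = 0.5 * 1.853,
                               ellipsoid = wgs84()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(species = character(), n = integer(),
                          geomean_km = numeric(), log_se = numeric(),
                          mean_recovery_years = numeric(),
                          n_floored = integer()))
  }
  d <- vincenty_km(records$band_lat, records$band_lon,
                   records$rec_lat, records$rec_lon, ellipsoid = ellipsoid)
  floored <- d < floor_km
  d[floored] <- floor_km
  records |>
    dplyr::mutate(.dist_km = d, .floored = floored,
                  .years = elapsed_years(.data$band_date, .data$rec_date)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      geomean_km = exp(mean(log(.data$.dist_km))),
      log_se = ifelse(dplyr::n() > 1,
                      stats::sd(log(.data$.dist_km)) / sqrt(dplyr::n()),
                      NA_real_),
      mean_recovery_years = mean(.data$.years),
      n_floored = sum(.data$.floored),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species)
}

#' Retain species with adequate sample sizes
#'
#' Standard errors of dispersal estimates blow up for species with very few
#' recoveries, so only species with at least `min_n` retained records enter
#' the comparative analysis (default 5, i.e. "sample size greater than
#' four").
#'
#' @param estimates Output of [estimate_dispersal()].
#' @param min_n Minimum record count; default 5.
#' @return The subset, ordered by species.
#' @export
retain_species <- function(estimates, min_n = 5) {
  stopifnot(min_n >= 1)
  estimates |>
    dplyr::filter(.data$n >= min_n) |>
    dplyr::arrange(.data$species)
}
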