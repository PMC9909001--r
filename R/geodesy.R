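#' WGS84 ellipsoid parameters
#'
#' Reference ellipsoid used for all geodesic distance computations.
#' Defaults to WGS84 (equatorial radius `a` = 6378137 m, flattening
#' `f` = 1/298.257223563).
#'
#' @param a Equatorial radius in meters; must be positive.
#' @param f Flattening (dimensionless); must satisfy `0 <= f < 1`.
#'
#' @return A list with components `a`, `b` (polar radius) and `f`,
#'   of class `ellipsoid`.
#' @export
#' @examples
#' wgs84()
wgs84 <- function(a = 6378137, f = 1 / 298.257223563) {
  stopifnot(is.numeric(a), length(a) == 1, a > 0,
            is.numeric(f), length(f) == 1, f >= 0, f < 1)
  structure(list(a = a, b = a * (1 - f), f = f), class = "ellipsoid")
}

#' Normalize longitudes to (-180, 180]
#'
#' @param lon Numeric vector of longitudes in decimal degrees.
#' @return Longitudes wrapped into (-180, 180].
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

validate_coords <- function(lat, lon, what = "coordinate") {
  bad_lat <- !is.finite(lat) | lat < -90 | lat > 90
  bad_lon <- !is.finite(lon) | lon < -360 | lon > 360
  if (any(bad_lat)) {
    stop("invalid ", what, " latitude(s): ",
         paste(utils::head(lat[bad_lat], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(bad_lon)) {
    stop("invalid ", what, " longitude(s): ",
         paste(utils::head(lon[bad_lon], 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Vincenty inverse geodesic distance
#'
#' Shortest distance between pairs of points on a reference ellipsoid,
#' computed with Vincenty's inverse iteration. All arguments are recycled
#' to a common length, so whole columns of banding/recovery coordinates
#' can be processed in one call.
#'
#' Near-antipodal pairs for which the iteration fails to converge raise an
#' error naming the offending pair; dispersal and migration distances never
#' approach antipodality in practice, so no silent fallback is attempted.
#'
#' @param lat1,lon1 Origin coordinates, decimal degrees.
#' @param lat2,lon2 Destination coordinates, decimal degrees.
#' @param ellipsoid Reference ellipsoid, see [wgs84()].
#' @param tol Convergence tolerance on the longitude-difference iterate
#'   (radians); default 1e-12.
#' @param max_iter Iteration cap; default 200.
#'
#' @return Numeric vector of distances in kilometers (full float
#'   precision; round only at report time).
#' @export
#' @examples
#' vincenty_km(0, 0, 0, 1)   # one equatorial degree, ~111.3195 km
#' vincenty_km(45, -75, 45, -75)  # identical points -> 0
vincenty_km <- function(lat1, lon1, lat2, lon2, ellipsoid = wgs84(),
                        tol = 1e-12, max_iter = 200L) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  validate_coords(lat1, lon1, "origin")
  validate_coords(lat2, lon2, "destination")
  lon1 <- normalize_lon(lon1)
  lon2 <- normalize_lon(lon2)

  a <- ellipsoid$a; b <- ellipsoid$b; f <- ellipsoid$f
  rad <- pi / 180
  U1 <- atan((1 - f) * tan(lat1 * rad))
  U2 <- atan((1 - f) * tan(lat2 * rad))
  L <- (lon2 - lon1) * rad
  # wrap the longitude difference into (-pi, pi]
  L <- ((L + pi) %% (2 * pi)) - pi

  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)

  same <- (abs(U1 - U2) < .Machine$double.eps * 4) & (abs(L) < .Machine$double.eps * 4)

  lambda <- L
  lambda_prev <- lambda + 10 * tol
  active <- !same
  sinSigma <- cosSigma <- sigma <- numeric(n)
  cosSqAlpha <- cos2SigmaM <- numeric(n)
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    i <- which(active)
    sinLambda <- sin(lambda[i]); cosLambda <- cos(lambda[i])
    ss <- sqrt((cosU2[i] * sinLambda)^2 +
               (cosU1[i] * sinU2[i] - sinU1[i] * cosU2[i] * cosLambda)^2)
    cs <- sinU1[i] * sinU2[i] + cosU1[i] * cosU2[i] * cosLambda
    sg <- atan2(ss, cs)
    sinAlpha <- ifelse(ss == 0, 0, cosU1[i] * cosU2[i] * sinLambda / ss)
    c2a <- 1 - sinAlpha^2
    c2sm <- ifelse(c2a == 0, 0, cs - 2 * sinU1[i] * sinU2[i] / c2a)
    Cc <- f / 16 * c2a * (4 + f * (4 - 3 * c2a))
    lambda_new <- L[i] + (1 - Cc) * f * sinAlpha *
      (sg + Cc * ss * (c2sm + Cc * cs * (-1 + 2 * c2sm^2)))
    sinSigma[i] <- ss; cosSigma[i] <- cs; sigma[i] <- sg
    cosSqAlpha[i] <- c2a; cos2SigmaM[i] <- c2sm
    converged <- abs(lambda_new - lambda[i]) < tol
    lambda[i] <- lambda_new
    active[i[converged]] <- FALSE
  }
  if (any(active)) {
    j <- which(active)[1]
    stop(sprintf(
      "Vincenty inverse failed to converge after %d iterations for near-antipodal pair (%.6f, %.6f) -> (%.6f, %.6f)",
      max_iter, lat1[j], lon1[j], lat2[j], lon2[j]), call. = FALSE)
  }

  uSq <- cosSqAlpha * (a^2 - b^2) / b^2
  A <- 1 + uSq / 16384 * (4096 + uSq * (-768 + uSq * (320 - 175 * uSq)))
  B <- uSq / 1024 * (256 + uSq * (-128 + uSq * (74 - 47 * uSq)))
  deltaSigma <- B * sinSigma *
    (cos2SigmaM + B / 4 * (cosSigma * (-1 + 2 * cos2SigmaM^2) -
       B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) * (-3 + 4 * cos2SigmaM^2)))
  d <- b * A * (sigma - deltaSigma)
  d[same] <- 0
  d / 1000
}

#' Geodesic distance between breeding- and wintering-range centroids
#'
#' Convenience wrapper used for species migration distances: one Vincenty
#' distance per row of a centroid table.
#'
#' @param centroids A data frame with columns `breed_lat`, `breed_lon`,
#'   `winter_lat`, `winter_lon` (decimal degrees).
#' @param ... Passed to [vincenty_km()].
#' @return The input as a tibble with a `migration_km` column appended.
#' @export
centroid_distance <- function(centroids, ...) {
  need <- c("breed_lat", "breed_lon", "winter_lat", "winter_lon")
  miss <- setdiff(need, names(centroids))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dplyr::mutate(tibble::as_tibble(centroids),
    migration_km = vincenty_km(.data$breed_lat, .data$breed_lon,
                               .data$winter_lat, .data$winter_lon, ...))
}
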