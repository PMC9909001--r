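# Fixtures and independent oracles shared across the suite.

# One-species metadata: breeding season May-Aug, range box 40-60N, 120-80W.
toy_meta <- function() {
  tibble::tibble(species = "A",
                 season_start_month = 5, season_end_month = 8,
                 lat_min = 40, lat_max = 60, lon_min = -120, lon_max = -80)
}

toy_record <- function(band_id, band_date = "2000-06-15",
                       band_lat = 45, band_lon = -100,
                       age_code = "nestling", rec_date = "2002-06-20",
                       rec_lat = 45.3, rec_lon = -100.2,
                       rec_condition = "found_dead", precision_code = 1) {
  tibble::tibble(band_id = band_id, species = "A",
                 band_date = as.Date(band_date), band_lat = band_lat,
                 band_lon = band_lon, age_code = age_code,
                 rec_date = as.Date(rec_date), rec_lat = rec_lat,
                 rec_lon = rec_lon, rec_condition = rec_condition,
                 precision_code = precision_code)
}

# 12 records: five clean, seven each violating exactly one filter.
toy_record_table <- function() {
  dplyr::bind_rows(
    toy_record("clean1"),
    toy_record("clean2", rec_lat = 46, rec_lon = -99),
    toy_record("clean3", band_lat = 50, rec_lat = 50.5, rec_lon = -100.4),
    toy_record("clean4", rec_date = "2003-07-01"),
    toy_record("clean5", rec_lat = 44.2),
    toy_record("bad_age", age_code = "adult"),
    toy_record("bad_maturity", band_date = "2000-08-01",
               rec_date = "2001-06-01"),
    toy_record("bad_band_season", band_date = "2000-03-15"),
    toy_record("bad_rec_season", rec_date = "2002-10-01"),
    toy_record("bad_range", rec_lat = 65),
    toy_record("bad_condition", rec_condition = "shot"),
    toy_record("bad_precision", precision_code = 10)
  )
}

# longitude offset (degrees) giving an exact equatorial distance in km
equator_deg_per_km <- function() 180 / (pi * 6378.137)

# independent phylogenetic-covariance oracle: walk each tip's root path
# in the edge matrix and sum the branch lengths the two paths share
brute_force_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  edge_of_child <- function(node) which(tree$edge[, 2] == node)
  path_edges <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      e <- edge_of_child(node)
      out <- c(out, e)
      node <- tree$edge[e, 1]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  }
  C
}

# direct multivariate-normal log-density oracle (solve/determinant based,
# no Cholesky shortcuts shared with the implementation)
mvn_loglik_oracle <- function(y, mean, Sigma) {
  n <- length(y)
  r <- y - mean
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       t(r) %*% solve(Sigma, r)))
}

# WGS84 meridian arc length (km) by direct numerical integration of the
# meridional radius of curvature
meridian_arc_km <- function(phi_deg, a = 6378137, f = 1 / 298.257223563) {
  e2 <- f * (2 - f)
  M <- function(phi) a * (1 - e2) / (1 - e2 * sin(phi)^2)^1.5
  stats::integrate(M, 0, phi_deg * pi / 180, rel.tol = 1e-12)$value / 1000
}

random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n)
}
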