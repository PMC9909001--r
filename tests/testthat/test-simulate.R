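test_that("simulated trees are ultrametric, sized and deterministic", {
  tr <- simulate_tree(3, depth = 2, seed = 1)
  expect_equal(ape::Ntip(tr), 3)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(depths), rep(2, 3), tolerance = 1e-10)
  expect_identical(ape::write.tree(simulate_tree(20, seed = 7)),
                   ape::write.tree(simulate_tree(20, seed = 7)))
  tr1 <- simulate_tree(15, depth = 1, seed = 3)
  tr3 <- simulate_tree(15, depth = 3, seed = 3)
  expect_equal(phylo_covariance(tr3), 3 * phylo_covariance(tr1),
               tolerance = 1e-10)
})

test_that("trait simulation is reproducible and carries its ground truth", {
  tr <- simulate_tree(20, seed = 4)
  a <- simulate_traits(tr, beta = c(x1 = 2, x2 = 0), lambda = 0.4,
                       sigma2 = 0.25, seed = 9)
  b <- simulate_traits(tr, beta = c(x1 = 2, x2 = 0), lambda = 0.4,
                       sigma2 = 0.25, seed = 9)
  expect_identical(a$traits, b$traits)
  expect_equal(a$truth$beta, c(x1 = 2, x2 = 0))
  expect_equal(colnames(a$traits), c("species", "x1", "x2", "y"))
  withcat <- simulate_traits(tr, beta = c(x1 = 1), n_categorical = 1,
                             seed = 10)
  expect_true(all(withcat$traits$cat1 %in%
                    c("coast", "open", "wetlands", "woodlands")))
})

test_that("independent-noise responses show no slope or signal on average", {
  ests <- t(vapply(1:50, function(s) {
    tr <- simulate_tree(30, seed = 300 + s)
    st <- simulate_traits(tr, beta = c(x1 = 0), lambda = 0, sigma2 = 1,
                          seed = 400 + s)
    f <- pgls(y ~ x1, st$traits, tr)
    c(coef(f)[["x1"]], f$lambda)
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1])), 0.1)
  expect_lt(median(ests[, 2]), 0.15)
})

test_that("contaminant records are removed by exactly their targeted filter", {
  cfg <- sim_config(seed = 5, n_species = 4, n_records = 100,
                    contamination = c(out_of_season = 0.1,
                                      out_of_range = 0.1, hunting = 0.1,
                                      coarse_precision = 0.1))
  sim <- simulate_study(cfg)
  filtered <- filter_records(sim$records, sim$meta)
  audit <- filter_audit(filtered)
  truth_counts <- table(sim$records$truth)
  removed <- stats::setNames(audit$removed$removed, audit$removed$filter)
  expect_equal(removed[["breeding_season"]],
               unname(truth_counts["out_of_season"]))
  expect_equal(removed[["breeding_range"]],
               unname(truth_counts["out_of_range"]))
  expect_equal(removed[["found_dead"]], unname(truth_counts["hunting"]))
  expect_equal(removed[["precision"]],
               unname(truth_counts["coarse_precision"]))
  expect_setequal(filtered$band_id,
                  sim$records$band_id[sim$records$truth == "clean"])
})

test_that("a zero-contamination table passes every filter", {
  cfg <- sim_config(seed = 6, n_species = 5, n_records = 150,
                    contamination = c(out_of_season = 0, out_of_range = 0,
                                      hunting = 0, coarse_precision = 0))
  sim <- simulate_study(cfg)
  filtered <- filter_records(sim$records, sim$meta)
  expect_equal(nrow(filtered), nrow(sim$records))
})

test_that("generators are pure functions of configuration and seed", {
  cfg <- sim_config(seed = 11, n_species = 5, n_records = 20)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$traits, s2$traits)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  s3 <- simulate_study(sim_config(seed = 12, n_species = 5, n_records = 20))
  expect_false(identical(s1$records, s3$records))
})

test_that("the full synthetic pipeline recovers the generating slope", {
  true_beta <- sim_config()$beta[["x1"]]
  beta_hats <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 5000 + s, n_species = 44, n_records = 200)
    sim <- simulate_study(cfg)
    est <- filter_records(sim$records, sim$meta) |>
      estimate_dispersal() |>
      retain_species(5)
    d <- est |>
      dplyr::mutate(log_dispersal = log(.data$geomean_km)) |>
      dplyr::left_join(sim$traits, by = "species")
    fit <- pgls(log_dispersal ~ x1, d, sim$tree)
    coef(fit)[["x1"]]
  }, numeric(1))
  # bias < 10% of the true slope
  expect_lt(abs(mean(beta_hats) - true_beta), 0.1 * true_beta)
})
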