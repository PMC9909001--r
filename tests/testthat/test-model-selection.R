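three_cont <- function() list(predictor_spec("A"), predictor_spec("B"),
                              predictor_spec("C"))

test_that("design preparation log-transforms, standardizes and recodes", {
  d <- tibble::tibble(species = c("a", "b", "c"),
                      x = c(1, exp(2), exp(4)),
                      h = c("open", "coast", "woodlands"))
  out <- prepare_predictors(
    d, list(predictor_spec("x", log_transform = TRUE),
            predictor_spec("h", role = "categorical", reference = "coast")))
  expect_equal(out$x, c(-1, 0, 1))
  expect_equal(mean(out$x), 0)
  expect_equal(sd(out$x), 1)
  expect_equal(levels(out$h), c("coast", "open", "woodlands"))
  X <- model.matrix(~h, out)
  expect_equal(ncol(X), 3)  # intercept + (levels - 1) indicators

  expect_error(prepare_predictors(
    d, list(predictor_spec("h", role = "categorical",
                           reference = "missing"))), "reference level")
  d$x[1] <- -1
  expect_error(prepare_predictors(
    d, list(predictor_spec("x", log_transform = TRUE))), "non-positive")
  d$x <- 5
  expect_error(prepare_predictors(d, list(predictor_spec("x"))),
               "zero-variance")
})

test_that("rows with missing values are dropped with an audit", {
  d <- tibble::tibble(species = c("a", "b", "c", "d"),
                      x = c(1, NA, 3, 4), y = c(1, 2, NA, 4))
  out <- prepare_predictors(d, list(predictor_spec("x")), response = "y")
  expect_equal(out$species, c("a", "d"))
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$species, c("b", "c"))
  expect_equal(dropped$column[dropped$species == "b"], "x")
})

test_that("model enumeration respects marginality and the variable cap", {
  models <- enumerate_models(three_cont(), max_terms = 5)
  # independent brute-force oracle: all main subsets x all interaction
  # subsets, kept when mains are present and the variable count fits
  oracle <- 0L
  mains_sets <- unlist(lapply(0:3, function(k)
    utils::combn(c("A", "B", "C"), k, simplify = FALSE)), recursive = FALSE)
  int_pool <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  int_sets <- unlist(lapply(0:3, function(k)
    utils::combn(int_pool, k, simplify = FALSE)), recursive = FALSE)
  for (m in mains_sets) for (is in int_sets) {
    ok <- all(vapply(is, function(p) all(p %in% m), TRUE)) &&
      length(m) + length(is) <= 5
    if (ok) oracle <- oracle + 1L
  }
  expect_equal(nrow(models), oracle)
  expect_equal(models$model[1], "1")
  expect_true("A + B + A:B" %in% models$model)
  expect_false(any(grepl("A:B.*A:C.*B:C", models$model)))  # 6 variables

  expect_equal(nrow(enumerate_models(list(predictor_spec("A")))), 2)
  expect_equal(enumerate_models(three_cont(), max_terms = 0)$model, "1")
  # categorical predictors never enter interactions
  specs <- list(predictor_spec("A"),
                predictor_spec("H", role = "categorical"))
  expect_false(any(grepl(":", enumerate_models(specs)$model)))
})

test_that("Akaike weights follow the exponential delta rule", {
  tr <- simulate_tree(20, seed = 50)
  st <- simulate_traits(tr, beta = c(x1 = 1.5, x2 = 0), seed = 51)
  f1 <- pgls(y ~ x1, st$traits, tr)
  f2 <- pgls(y ~ x2, st$traits, tr)
  ms <- rank_models(list(x1 = f1, x2 = f2))
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(ms$table$delta_AICc[1], 0)
  d <- ms$table$delta_AICc[2]
  expect_equal(ms$table$weight[2] / ms$table$weight[1], exp(-d / 2),
               tolerance = 1e-12)

  # frozen hand value: deltas {0, 2} -> weights {0.7311, 0.2689}
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(round(w, 4), c(0.7311, 0.2689))

  bad <- pgls(y ~ x1, st$traits[-1, ], ape::drop.tip(tr, st$traits$species[1]))
  expect_error(rank_models(list(a = f1, b = bad)), "row sets")
})

test_that("confidence sets keep the smallest prefix reaching the level", {
  # synthetic model_set with known weights {0.6, 0.3, 0.08, 0.02}
  tab <- tibble::tibble(model = c("m1", "m2", "m3", "m4"),
                        k = 3:6, lambda = 0.5,
                        logLik = 0, AICc = -2 * log(c(0.6, 0.3, 0.08, 0.02)),
                        r.squared = 0.1)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$weight <- c(0.6, 0.3, 0.08, 0.02)
  tab$cum_weight <- cumsum(tab$weight)
  ms <- structure(list(table = tab, fits = list()), class = "model_set")
  expect_equal(confidence_set(ms, 0.95)$model, c("m1", "m2", "m3"))
  expect_equal(confidence_set(ms, 1)$model, tab$model)
  one <- structure(list(table = tab[1, ] |>
                          dplyr::mutate(weight = 1, cum_weight = 1),
                        fits = list()), class = "model_set")
  expect_equal(nrow(confidence_set(one)), 1)
})

test_that("variable importance sums weights over containing models", {
  tab <- tibble::tibble(model = c("A + B", "A"), k = c(4L, 3L),
                        lambda = 0.5, logLik = 0, AICc = c(0, 1.69),
                        r.squared = 0.2,
                        delta_AICc = c(0, 1.69))
  tab$weight <- c(0.7, 0.3)
  tab$cum_weight <- cumsum(tab$weight)
  ms <- structure(list(table = tab, fits = list()), class = "model_set")
  imp <- variable_importance(ms)
  expect_equal(imp$importance[imp$variable == "A"], 1)
  expect_equal(imp$importance[imp$variable == "B"], 0.7)
  expect_equal(variable_importance(ms, "Q")$importance, 0)
  # interactions count toward their constituent variables
  tab$model <- c("A + B + A:B", "B")
  ms2 <- structure(list(table = tab, fits = list()), class = "model_set")
  expect_equal(variable_importance(ms2, "A")$importance, 0.7)
})

test_that("ranking statistics are invariant to a constant AICc shift", {
  tr <- simulate_tree(22, seed = 60)
  st <- simulate_traits(tr, beta = c(x1 = 1, x2 = 0), seed = 61)
  specs <- list(predictor_spec("x1"), predictor_spec("x2"))
  ms <- fit_model_set(st$traits, tr, "y", specs)
  shifted <- ms
  shifted$table$AICc <- shifted$table$AICc + 17
  shifted$table$delta_AICc <- shifted$table$AICc - min(shifted$table$AICc)
  w <- exp(-shifted$table$delta_AICc / 2)
  shifted$table$weight <- w / sum(w)
  expect_equal(shifted$table$weight, ms$table$weight, tolerance = 1e-12)
  expect_equal(variable_importance(shifted), variable_importance(ms),
               tolerance = 1e-12)
  expect_equal(confidence_set(shifted)$model, confidence_set(ms)$model)
})

test_that("model averaging reports conditional and full flavors", {
  tr <- simulate_tree(25, seed = 70)
  st <- simulate_traits(tr, beta = c(x1 = 1, x2 = 0.5), seed = 71)
  specs <- list(predictor_spec("x1"), predictor_spec("x2"))
  ms <- fit_model_set(st$traits, tr, "y", specs, interactions = FALSE)
  avg <- model_average(ms)
  # terms present in every model coincide across flavors
  icpt <- avg[avg$term == "(Intercept)", ]
  expect_equal(icpt$weight_sum, 1, tolerance = 1e-12)
  expect_equal(icpt$estimate_cond, icpt$estimate_full)
  # full average shrinks toward zero by the missing weight
  x1 <- avg[avg$term == "x1", ]
  expect_equal(x1$estimate_full, x1$estimate_cond * x1$weight_sum,
               tolerance = 1e-10)
  expect_lt(abs(x1$estimate_full), abs(x1$estimate_cond))
  expect_equal(x1$conf.high_cond, x1$estimate_cond + 1.96 * x1$se_cond)

  # hand-checkable weighted means on a synthetic two-model set
  w <- c(0.75, 0.25); b <- c(1, 3)
  expect_equal(sum(w * b / sum(w)), 1.5)
  expect_equal(sum(w * c(1, 0)), 0.75)
})

test_that("single-model sets average to that model's coefficients", {
  tr <- simulate_tree(20, seed = 75)
  st <- simulate_traits(tr, beta = c(x1 = 1), seed = 76)
  f <- pgls(y ~ x1, st$traits, tr)
  ms <- rank_models(list(`x1` = f))
  avg <- model_average(ms)
  expect_equal(avg$estimate_cond[match(c("(Intercept)", "x1"), avg$term)],
               unname(coef(f)))
})

test_that("GVIF matches determinant arithmetic and the car oracle", {
  # orthogonal continuous predictors -> exactly 1
  d <- tibble::tibble(species = letters[1:8],
                      A = c(1, 1, 1, 1, -1, -1, -1, -1),
                      B = c(1, -1, 1, -1, 1, -1, 1, -1),
                      y = rnorm(8))
  g <- gvif(d, list(predictor_spec("A", standardize = FALSE),
                    predictor_spec("B", standardize = FALSE)))
  expect_equal(g$gvif, c(1, 1), tolerance = 1e-12)
  expect_equal(g$gvif_corrected, c(1, 1), tolerance = 1e-12)

  # corrected value: GVIF 4 with df 1 -> 2; band on corrected^2
  expect_equal(4^(1 / (2 * 1)), 2)

  set.seed(80)
  n <- 60
  A <- rnorm(n); B <- 0.8 * A + sqrt(1 - 0.64) * rnorm(n); Cc <- rnorm(n)
  h <- sample(c("coast", "open", "wet"), n, replace = TRUE)
  d2 <- tibble::tibble(species = paste0("s", 1:n), A = A, B = B, C = Cc,
                       h = h, y = A + rnorm(n))
  specs <- list(predictor_spec("A"), predictor_spec("B"),
                predictor_spec("C"),
                predictor_spec("h", role = "categorical"))
  prep <- prepare_predictors(d2, specs)
  g2 <- gvif(prep, specs)
  expect_true(all(g2$gvif >= 1 - 1e-9))
  expect_equal(g2$df, c(1L, 1L, 1L, 2L))
  skip_if_not_installed("car")
  ref <- car::vif(lm(y ~ A + B + C + h, data = prep))
  expect_equal(g2$gvif, unname(ref[c("A", "B", "C", "h"), "GVIF"]),
               tolerance = 1e-8)

  d2$B2 <- d2$B
  expect_error(gvif(dplyr::mutate(prep, B2 = B),
                    c(specs, list(predictor_spec("B2")))), "singular")
})

test_that("the true predictor dominates importance in synthetic replicates", {
  wins <- vapply(1:30, function(s) {
    tr <- simulate_tree(44, seed = 9000 + s)
    st <- simulate_traits(tr, beta = c(x1 = 2, x2 = 0, x3 = 0, x4 = 0),
                          lambda = 0.4, sigma2 = 0.25, seed = 9100 + s)
    specs <- lapply(paste0("x", 1:4), predictor_spec)
    ms <- fit_model_set(st$traits, tr, "y", specs, interactions = FALSE)
    imp <- variable_importance(ms)
    imp$variable[which.max(imp$importance)] == "x1"
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
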