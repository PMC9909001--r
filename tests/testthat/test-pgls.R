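test_that("GLS with identity covariance reproduces ordinary least squares", {
  set.seed(1)
  n <- 25
  X <- cbind(1, x = rnorm(n))
  y <- 1 + 2 * X[, 2] + rnorm(n)
  fit <- gls_fit(X, y, diag(n))
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("GLS log-likelihood equals the direct multivariate-normal density", {
  for (seed in c(3, 4, 5)) {
    tr <- random_tree(10, seed = seed)
    C <- phylo_covariance(tr)
    set.seed(seed + 100)
    X <- cbind(1, x = rnorm(10))
    y <- as.numeric(X %*% c(1, 0.5)) + rnorm(10)
    V <- lambda_transform(C, 0.7)
    fit <- gls_fit(X, y, V)
    direct <- mvn_loglik_oracle(y, as.numeric(X %*% fit$beta),
                                fit$sigma2 * V)
    expect_equal(fit$logLik, direct, tolerance = 1e-8)
  }
})

test_that("perfect linear data give exact coefficients and zero residual", {
  tr <- random_tree(12, seed = 8)
  C <- phylo_covariance(tr)
  X <- cbind(1, x = seq_len(12))
  y <- as.numeric(X %*% c(2, -3))
  fit <- gls_fit(X, y, lambda_transform(C, 0.5))
  expect_equal(unname(fit$beta), c(2, -3), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-16)
})

test_that("rank-deficient designs and singular covariances are named", {
  X <- cbind(`(Intercept)` = 1, a = 1:10, b = 2 * (1:10))
  expect_error(gls_fit(X, rnorm(10), diag(10)), "aliased columns: b")
  expect_error(gls_fit(cbind(1, 1:4), rnorm(4), matrix(1, 4, 4)),
               "positive definite")
})

test_that("pgls matches nlme::gls with a fixed Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(30, seed = 5)
  st <- simulate_traits(tr, beta = c(x1 = 1.5), lambda = 0.6,
                        sigma2 = 0.3, seed = 7)
  d <- as.data.frame(st$traits)
  fit <- pgls(y ~ x1, d, tr, lambda = 0.6)
  ref <- nlme::gls(y ~ x1, data = d,
                   correlation = ape::corPagel(0.6, phy = tr,
                                               form = ~species, fixed = TRUE),
                   method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("profile likelihood at the ML lambda dominates fixed-lambda fits", {
  tr <- simulate_tree(40, seed = 10)
  st <- simulate_traits(tr, beta = c(x1 = 1), lambda = 0.5, sigma2 = 0.4,
                        seed = 11)
  fit <- pgls(y ~ x1, st$traits, tr)
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_gte(fit$logLik + 1e-9,
               pgls(y ~ x1, st$traits, tr, lambda = lam)$logLik)
  }
})

test_that("lambda and slopes are invariant to rescaling branch lengths", {
  tr <- simulate_tree(35, seed = 14)
  st <- simulate_traits(tr, beta = c(x1 = 1.2), lambda = 0.5,
                        sigma2 = 0.3, seed = 15)
  f1 <- pgls(y ~ x1, st$traits, tr)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 7.3
  f2 <- pgls(y ~ x1, st$traits, tr2)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
  expect_equal(f2$sigma2, f1$sigma2 / 7.3, tolerance = 1e-4)
})

test_that("ML lambda recovers independent-noise and Brownian extremes", {
  lam_hat <- function(true_lambda, seeds) {
    vapply(seeds, function(s) {
      tr <- simulate_tree(44, seed = s)
      st <- simulate_traits(tr, beta = c(x1 = 0), lambda = true_lambda,
                            sigma2 = 1, seed = s + 1000)
      pgls(y ~ 1, st$traits, tr)$lambda
    }, numeric(1))
  }
  expect_lt(median(lam_hat(0, 1:100)), 0.1)
  expect_gt(median(lam_hat(1, 1:100)), 0.9)
})

test_that("two taxa cannot identify lambda", {
  d <- tibble::tibble(species = c("A", "B"), y = c(1, 2))
  expect_error(pgls(y ~ 1, d, "(A:1,B:1);"), "unidentifiable")
})

test_that("AICc follows the small-sample correction and its limits", {
  expect_equal(aicc(0, 2, 43), 4.3)
  expect_lt(aicc(-10, 3, 30), aicc(-12, 3, 30))
  expect_equal(aicc(-5, 3, 1e9), -2 * (-5) + 6, tolerance = 1e-6)
  expect_error(aicc(0, 5, 6), "n must exceed")
})

test_that("R-squared spans the intercept-only and perfect-fit extremes", {
  tr <- simulate_tree(20, seed = 20)
  st <- simulate_traits(tr, beta = c(x1 = 2), lambda = 0.3, sigma2 = 0.2,
                        seed = 21)
  expect_equal(pgls(y ~ 1, st$traits, tr)$r_squared, 0)
  d <- st$traits
  d$y <- 1 + 2 * d$x1
  expect_equal(pgls(y ~ x1, d, tr, lambda = 0.4)$r_squared, 1,
               tolerance = 1e-9)
  # with lambda = 0 on a star tree the definition reduces to OLS R^2
  star <- ape::stree(20, type = "star")
  star$edge.length <- rep(1, 20)
  star$tip.label <- st$traits$species
  f <- pgls(y ~ x1, st$traits, star, lambda = 0)
  expect_equal(f$r_squared, summary(lm(y ~ x1, st$traits))$r.squared,
               tolerance = 1e-10)
  expect_equal(unname(coef(f)), unname(coef(lm(y ~ x1, st$traits))),
               tolerance = 1e-10)
})

test_that("phylogenetic signal test behaves at both ends", {
  tr <- simulate_tree(44, seed = 30)
  white <- simulate_traits(tr, beta = c(x1 = 0), lambda = 0, sigma2 = 1,
                           seed = 31)
  s0 <- phylo_signal(white$traits, tr, value = "y")
  expect_lt(s0$lambda, 0.25)
  expect_gte(s0$LR, 0)
  bm <- simulate_traits(tr, beta = c(x1 = 0), lambda = 1, sigma2 = 1,
                        seed = 32)
  s1 <- phylo_signal(bm$traits, tr, value = "y")
  expect_gt(s1$lambda, 0.8)
  expect_lt(s1$p.value, 0.05)
  y <- setNames(bm$traits$y, bm$traits$species)
  expect_equal(phylo_signal(y, tr), s1)
})

test_that("tidy and glance summarize a fit consistently", {
  tr <- simulate_tree(25, seed = 40)
  st <- simulate_traits(tr, beta = c(x1 = 1), seed = 41)
  fit <- pgls(y ~ x1, st$traits, tr)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x1"))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- glance(fit)
  expect_equal(gl$AICc, aicc(gl$logLik, gl$k, gl$n))
  expect_equal(gl$k, 4)  # 2 coefficients + sigma2 + lambda
})
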