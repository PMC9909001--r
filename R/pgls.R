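#' Generalized least squares with a fixed covariance
#'
#' Core GLS solver used by [pgls()]. Estimates
#' `beta = (X' V^-1 X)^-1 X' V^-1 y` via a Cholesky whitening of `V`,
#' with the maximum-likelihood error variance `sigma2 = RSS_w / n`
#' (RSS on the whitened scale) profiled out of the Gaussian
#' log-likelihood. Coefficient standard errors use the unbiased variance
#' `RSS_w / (n - p)`.
#'
#' @param X Design matrix (n x p, full column rank).
#' @param y Response vector, length n.
#' @param V Positive-definite covariance structure (n x n), e.g. a
#'   lambda-transformed phylogenetic covariance.
#' @return A list: `beta`, `se`, `sigma2` (ML), `logLik`, `rss`
#'   (whitened residual sum of squares), `fitted`, `residuals`,
#'   `df.residual`.
#' @export
gls_fit <- function(X, y, V) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  if (n <= ncol(X)) stop("need more observations than coefficients", call. = FALSE)
  L <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix is not positive definite: ", conditionMessage(e),
         call. = FALSE)
  })
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / n
  ldetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + ldetV + n)
  R <- qr.R(qrX)[, order(qrX$pivot), drop = FALSE]
  XtViX_inv <- chol2inv(chol(crossprod(R)))
  sigma2_u <- rss / (n - ncol(X))
  se <- sqrt(diag(XtViX_inv) * sigma2_u)
  names(se) <- names(beta) <- colnames(X)
  fitted <- as.numeric(X %*% beta)
  list(beta = as.numeric(beta) |> stats::setNames(colnames(X)),
       se = se, sigma2 = sigma2, logLik = ll, rss = rss,
       fitted = fitted, residuals = y - fitted, df.residual = n - ncol(X))
}

# profile log-likelihood over Pagel's lambda: coarse grid then bounded
# refinement around the grid optimum
profile_lambda <- function(X, y, C, grid_n = 101, tol = 1e-6) {
  ll_at <- function(lam) gls_fit(X, y, lambda_transform(C, lam))$logLik
  grid <- seq(0, 1, length.out = grid_n)
  lls <- vapply(grid, ll_at, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(grid_n, i + 1)]
  opt <- stats::optimize(ll_at, lower = lo, upper = hi,
                         maximum = TRUE, tol = tol)
  if (opt$objective >= lls[i]) {
    list(lambda = opt$maximum, logLik = opt$objective)
  } else {
    list(lambda = grid[i], logLik = lls[i])
  }
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model whose error covariance is the phylogenetic
#' covariance of the tips transformed by Pagel's lambda,
#' `V = lambda_transform(C, lambda)`, by maximum likelihood. `lambda` is
#' either profiled over `[0, 1]` (grid of 101 points followed by bounded
#' refinement to tolerance 1e-6) or held fixed. The error variance is
#' profiled out analytically.
#'
#' The coefficient of determination follows the null-comparison
#' convention: `R^2 = 1 - RSS_model / SS_null`, where `SS_null` is the
#' whitened residual sum of squares of an intercept-only GLS using the
#' same lambda (hence the same correlation structure) as the model.
#'
#' The AICc parameter count is the number of regression coefficients
#' plus one for the error variance, plus one more when lambda is
#' estimated.
#'
#' @param formula Model formula.
#' @param data Data frame of traits, one row per taxon.
#' @param tree Phylogeny (`ape::phylo`, Newick string or path), or a
#'   precomputed covariance matrix whose dimnames are taxa.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param taxa Column of `data` holding taxon names (default
#'   `"species"`); row names are used if the column is absent.
#'
#' @return An object of class `pgls_fit`; see [tidy.pgls_fit()] and
#'   [glance.pgls_fit()] for tibble summaries.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
#' d <- tibble::tibble(species = c("A", "B", "C", "D"),
#'                     x = c(0, 1, 2, 3), y = c(0.1, 1.2, 1.9, 3.1))
#' fit <- pgls(y ~ x, d, tr)
#' glance(fit)
pgls <- function(formula, data, tree, lambda = "ML", taxa = "species") {
  data <- as.data.frame(data)
  taxa_vec <- if (taxa %in% names(data)) {
    normalize_taxon_names(as.character(data[[taxa]]))
  } else {
    normalize_taxon_names(rownames(data))
  }
  if (anyDuplicated(taxa_vec)) stop("duplicate taxa in data", call. = FALSE)
  C <- if (is.matrix(tree)) {
    missing <- setdiff(taxa_vec, rownames(tree))
    if (length(missing)) stop("taxa absent from covariance matrix: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    tree[taxa_vec, taxa_vec, drop = FALSE]
  } else {
    phylo_covariance(tree, order = taxa_vec)
  }
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  n <- length(y); p <- ncol(X)
  ml_lambda <- identical(lambda, "ML")
  if (ml_lambda && n < 3) {
    stop("lambda is unidentifiable with fewer than 3 taxa; fix lambda instead",
         call. = FALSE)
  }

  if (ml_lambda) {
    prof <- profile_lambda(X, y, C)
    lam <- prof$lambda
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be \"ML\" or a value in [0, 1]", call. = FALSE)
    }
    lam <- lambda
  }
  fit <- gls_fit(X, y, lambda_transform(C, lam))

  # null (intercept-only) fit under the same correlation structure
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  ss_null <- if (p == 1 && all(X == 1)) fit$rss else
    gls_fit(X0, y, lambda_transform(C, lam))$rss
  r2 <- 1 - fit$rss / ss_null

  k <- p + 1L + as.integer(ml_lambda)
  tval <- fit$beta / fit$se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  structure(list(
    formula = formula, taxa = taxa_vec, n = n, k = k,
    coefficients = fit$beta, se = fit$se, statistic = tval, p.value = pval,
    lambda = lam, lambda_ml = ml_lambda, sigma2 = fit$sigma2,
    logLik = fit$logLik, AICc = aicc(fit$logLik, k, n),
    rss = fit$rss, ss_null = ss_null, r_squared = r2,
    fitted = fit$fitted, residuals = fit$residuals,
    df.residual = fit$df.residual, response = y, design = X, C = C
  ), class = "pgls_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`; converges to AIC as
#' `n` grows.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(0, 2, 43)  # 4.3
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Phylogenetic signal in a trait (Pagel's lambda)
#'
#' Fits an intercept-only PGLS with lambda estimated by maximum
#' likelihood and tests it against the lambda = 0 (no signal) fit with a
#' likelihood-ratio statistic. Because lambda = 0 lies on the boundary of
#' the parameter space, the p-value uses the 50:50 mixture of a point
#' mass at zero and a chi-square with 1 df.
#'
#' @param trait Named numeric vector (names are taxa) or a data frame
#'   with `taxa` and `trait` columns given by `taxa`/`value`.
#' @param tree Phylogeny or covariance matrix, as in [pgls()].
#' @param taxa,value Column names when `trait` is a data frame.
#' @return A one-row tibble: `lambda`, `logLik`, `logLik0`, `LR`,
#'   `p.value`, `n`.
#' @export
phylo_signal <- function(trait, tree, taxa = "species", value = "trait") {
  if (is.data.frame(trait)) {
    df <- tibble::tibble(species = as.character(trait[[taxa]]),
                         y = as.numeric(trait[[value]]))
  } else {
    if (is.null(names(trait))) stop("trait vector must be named by taxon",
                                    call. = FALSE)
    df <- tibble::tibble(species = names(trait), y = as.numeric(trait))
  }
  f1 <- pgls(y ~ 1, df, tree, lambda = "ML")
  f0 <- pgls(y ~ 1, df, tree, lambda = 0)
  lr <- max(0, 2 * (f1$logLik - f0$logLik))
  p <- if (lr <= .Machine$double.eps^0.5) 1 else
    0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  tibble::tibble(lambda = f1$lambda, logLik = f1$logLik,
                 logLik0 = f0$logLik, LR = lr, p.value = p, n = f1$n)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda",
      if (x$lambda_ml) "by ML" else "fixed", ")\n")
  cat("  ", deparse(x$formula), " | n = ", x$n, "\n", sep = "")
  cat(sprintf("  lambda = %.4f, sigma2 = %.4g, logLik = %.3f, AICc = %.3f, R2 = %.4f\n",
              x$lambda, x$sigma2, x$logLik, x$AICc, x$r_squared))
  print(tidy(x))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic` (t, `n - p` df), `p.value`.
#' @exportS3Method generics::tidy
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$statistic),
                 p.value = unname(x$p.value))
}

#' One-row summary of a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `k`, `lambda`, `sigma2`, `logLik`, `AICc`,
#'   `r.squared`, `rss`.
#' @exportS3Method generics::glance
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, lambda = x$lambda, sigma2 = x$sigma2,
                 logLik = x$logLik, AICc = x$AICc,
                 r.squared = x$r_squared, rss = x$rss)
}
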