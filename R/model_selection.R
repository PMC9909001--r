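#' Declare a predictor for design preparation and model enumeration
#'
#' @param name Column name in the trait table.
#' @param role `"continuous"`, `"binary"` or `"categorical"`.
#' @param log_transform Natural-log transform before standardizing
#'   (continuous only).
#' @param standardize Z-score (subtract mean, divide by one sample
#'   standard deviation) before analysis (continuous only; default TRUE).
#' @param reference Reference level (categorical only); defaults to the
#'   first level alphabetically.
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(name,
                           role = c("continuous", "binary", "categorical"),
                           log_transform = FALSE, standardize = TRUE,
                           reference = NULL) {
  role <- match.arg(role)
  if (role != "continuous" && (log_transform || !is.null(reference) && role == "binary")) {
    if (log_transform) stop("log_transform applies to continuous predictors only",
                            call. = FALSE)
  }
  structure(list(name = name, role = role, log_transform = log_transform,
                 standardize = standardize && role == "continuous",
                 reference = reference),
            class = "predictor_spec")
}

#' Prepare a trait table for phylogenetic regression
#'
#' Applies, per predictor: natural-log transform where flagged, then
#' z-scoring (mean 0, sample standard deviation 1); binary predictors are
#' coerced to 0/1; categorical predictors become factors with the
#' configured reference level first (reference coding). Rows with missing
#' values in the response or any used predictor are dropped and recorded
#' in the `"dropped"` attribute, mirroring the attrition a real
#' species-level analysis reports.
#'
#' @param data Trait table (one row per taxon).
#' @param specs List of [predictor_spec()]s.
#' @param response Optional response column name included in the
#'   missingness screen.
#' @return The prepared tibble, with attribute `"dropped"` (tibble of
#'   dropped rows and the offending column).
#' @export
prepare_predictors <- function(data, specs, response = NULL) {
  data <- tibble::as_tibble(data)
  names(specs) <- vapply(specs, `[[`, "", "name")
  used <- c(response, names(specs))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("columns absent from data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  na_col <- apply(is.na(data[used]), 1, function(z)
    if (any(z)) used[which(z)[1]] else NA_character_)
  dropped <- tibble::tibble(row = which(!is.na(na_col)),
                            column = na_col[!is.na(na_col)])
  if ("species" %in% names(data)) {
    dropped$species <- data$species[dropped$row]
  }
  out <- data[is.na(na_col), , drop = FALSE]
  for (s in specs) {
    v <- out[[s$name]]
    if (s$role == "continuous") {
      v <- as.numeric(v)
      if (s$log_transform) {
        if (any(v <= 0)) stop("non-positive values in '", s$name,
                              "' under log transform", call. = FALSE)
        v <- log(v)
      }
      if (length(v) > 1 && stats::sd(v) == 0)
        stop("zero-variance predictor: ", s$name, call. = FALSE)
      if (s$standardize) v <- (v - mean(v)) / stats::sd(v)
    } else if (s$role == "binary") {
      v <- as.integer(as.logical(v))
      if (length(unique(v)) < 2) stop("zero-variance predictor: ", s$name,
                                      call. = FALSE)
    } else {
      v <- as.factor(as.character(v))
      if (nlevels(v) < 2) stop("categorical predictor '", s$name,
                               "' has fewer than 2 levels", call. = FALSE)
      ref <- s$reference %||% sort(levels(v))[1]
      if (!ref %in% levels(v)) stop("reference level '", ref,
                                    "' absent from '", s$name, "'",
                                    call. = FALSE)
      v <- stats::relevel(v, ref = ref)
    }
    out[[s$name]] <- v
  }
  attr(out, "dropped") <- dropped
  out
}

#' Enumerate candidate models (all subsets with marginal interactions)
#'
#' Builds every main-effect subset of the declared predictors with at most
#' `max_terms` variables, plus pairwise interactions restricted to
#' continuous and binary predictors, included only when both main effects
#' are present (marginality), an interaction counting as one additional
#' variable toward the cap. The intercept-only model is always included.
#' Order is deterministic: by variable count, then formula text.
#'
#' @param specs List of [predictor_spec()]s.
#' @param max_terms Cap on the number of variables per model (default 5).
#' @param interactions Include second-order effects (default TRUE).
#' @return A tibble: `model` (right-hand-side text, `"1"` for the
#'   intercept-only model), `terms` (list of term labels), `n_vars`.
#' @export
enumerate_models <- function(specs, max_terms = 5, interactions = TRUE) {
  nm <- sort(vapply(specs, `[[`, "", "name"))
  roles <- stats::setNames(vapply(specs, `[[`, "", "role"),
                           vapply(specs, `[[`, "", "name"))
  subsets <- function(x) {
    do.call(c, lapply(0:length(x), function(k)
      utils::combn(x, k, simplify = FALSE)))
  }
  out <- list()
  for (mains in subsets(nm)) {
    if (length(mains) > max_terms) next
    out[[length(out) + 1]] <- mains
    if (!interactions || length(mains) < 2) next
    eligible <- mains[roles[mains] %in% c("continuous", "binary")]
    if (length(eligible) < 2) next
    pairs <- utils::combn(eligible, 2, function(p)
      paste(p, collapse = ":"), simplify = TRUE)
    for (ints in subsets(pairs)) {
      if (length(ints) == 0) next
      if (length(mains) + length(ints) > max_terms) next
      out[[length(out) + 1]] <- c(mains, ints)
    }
  }
  tab <- tibble::tibble(
    terms = out,
    model = vapply(out, function(t)
      if (length(t) == 0) "1" else paste(t, collapse = " + "), ""),
    n_vars = lengths(out)
  )
  tab <- tab[order(tab$n_vars, tab$model), c("model", "terms", "n_vars")]
  tab
}

#' Rank fitted models by AICc
#'
#' Computes per-model AICc differences to the best model and Akaike
#' weights `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` (relative model
#' probabilities). Ties are broken by fewer parameters, then by formula
#' text. All fits must share the same taxa (identical row sets), or the
#' likelihoods are not comparable.
#'
#' @param fits Named list of `pgls_fit` objects (names are model labels).
#' @return A `model_set`: list with `table` (ranked tibble: `model`, `k`,
#'   `lambda`, `logLik`, `AICc`, `delta_AICc`, `weight`, `r.squared`,
#'   `cum_weight`) and `fits` (the list, in ranked order).
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) deparse(f$formula[[3]]), "")
  }
  taxa0 <- sort(fits[[1]]$taxa)
  same <- vapply(fits, function(f) identical(sort(f$taxa), taxa0), TRUE)
  if (!all(same)) {
    stop("fits use different row sets; likelihoods are not comparable",
         call. = FALSE)
  }
  tab <- tibble::tibble(
    model = names(fits),
    k = unname(vapply(fits, `[[`, 0L, "k")),
    lambda = unname(vapply(fits, `[[`, 0, "lambda")),
    logLik = unname(vapply(fits, `[[`, 0, "logLik")),
    AICc = unname(vapply(fits, `[[`, 0, "AICc")),
    r.squared = unname(vapply(fits, `[[`, 0, "r_squared"))
  )
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  ord <- order(tab$delta_AICc, tab$k, tab$model)
  tab <- tab[ord, ]
  tab$cum_weight <- cumsum(tab$weight)
  structure(list(table = tab, fits = fits[ord]), class = "model_set")
}

#' Fit and rank an all-subsets PGLS model set
#'
#' Enumerates candidate models with [enumerate_models()], fits each by
#' PGLS with lambda re-estimated by maximum likelihood per model, and
#' ranks the set by AICc.
#'
#' @param data Prepared trait table (see [prepare_predictors()]).
#' @param tree Phylogeny or covariance matrix.
#' @param response Response column name.
#' @param specs List of [predictor_spec()]s.
#' @inheritParams enumerate_models
#' @inheritParams pgls
#' @return A `model_set` (see [rank_models()]), with the enumeration
#'   table in `$models`.
#' @export
fit_model_set <- function(data, tree, response, specs, max_terms = 5,
                          interactions = TRUE, lambda = "ML",
                          taxa = "species") {
  models <- enumerate_models(specs, max_terms = max_terms,
                             interactions = interactions)
  C <- if (is.matrix(tree)) tree else {
    tvec <- normalize_taxon_names(as.character(data[[taxa]]))
    phylo_covariance(tree, order = tvec)
  }
  fits <- lapply(models$model, function(rhs) {
    f <- stats::as.formula(paste(response, "~", rhs))
    pgls(f, data, C, lambda = lambda, taxa = taxa)
  })
  names(fits) <- models$model
  ms <- rank_models(fits)
  ms$models <- models
  ms
}

#' 95% confidence model set
#'
#' The smallest prefix of the weight-ranked models whose cumulative
#' Akaike weight reaches the confidence level.
#'
#' @param ms A `model_set`.
#' @param level Cumulative-probability level (default 0.95).
#' @return The subset of the ranked table.
#' @export
confidence_set <- function(ms, level = 0.95) {
  stopifnot(inherits(ms, "model_set"), level > 0, level <= 1)
  tab <- ms$table[order(-ms$table$weight, ms$table$k, ms$table$model), ]
  cut <- which(cumsum(tab$weight) >= level - 1e-12)[1]
  if (is.na(cut)) cut <- nrow(tab)
  tab[seq_len(cut), ]
}

term_contains <- function(term, var) {
  vapply(strsplit(term, ":", fixed = TRUE),
         function(parts) var %in% parts, TRUE)
}

model_contains <- function(model_rhs, var) {
  if (model_rhs == "1") return(FALSE)
  terms <- strsplit(model_rhs, " + ", fixed = TRUE)[[1]]
  any(term_contains(terms, var))
}

#' Variable importance from Akaike weights
#'
#' Importance of a predictor is the sum of the weights (model
#' probabilities) of every model containing it, as a main effect or
#' inside an interaction.
#'
#' @param ms A `model_set`.
#' @param variables Predictor names; default: every name occurring in
#'   the set's formulas.
#' @return A tibble `variable`, `importance`, sorted decreasing.
#' @export
variable_importance <- function(ms, variables = NULL) {
  stopifnot(inherits(ms, "model_set"))
  tab <- ms$table
  if (is.null(variables)) {
    all_terms <- unlist(strsplit(tab$model[tab$model != "1"], " + ",
                                 fixed = TRUE))
    variables <- sort(unique(unlist(strsplit(all_terms, ":", fixed = TRUE))))
  }
  imp <- vapply(variables, function(v)
    sum(tab$weight[vapply(tab$model, model_contains, TRUE, var = v)]),
    numeric(1))
  tibble::tibble(variable = variables, importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Model-averaged coefficients
#'
#' Averages coefficients across the model set, reporting both flavors:
#' conditional averaging (weights renormalized over the models that
#' contain the term) and full averaging (a model lacking the term
#' contributes a zero coefficient). Unconditional standard errors follow
#' the usual multimodel formula
#' `SE = sum_i w_i * sqrt(se_i^2 + (b_i - b_bar)^2)`; 95% confidence
#' intervals are `estimate +/- 1.96 SE`.
#'
#' @param ms A `model_set`.
#' @return A tibble with one row per coefficient: `term`, `weight_sum`,
#'   `estimate_cond`, `se_cond`, `conf.low_cond`, `conf.high_cond`,
#'   `estimate_full`, `se_full`, `conf.low_full`, `conf.high_full`.
#' @export
model_average <- function(ms) {
  stopifnot(inherits(ms, "model_set"))
  w <- ms$table$weight
  coefs <- lapply(ms$fits, tidy)
  terms <- unique(unlist(lapply(coefs, `[[`, "term")))
  rows <- lapply(terms, function(tm) {
    est <- se <- rep(0, length(coefs))
    has <- logical(length(coefs))
    for (i in seq_along(coefs)) {
      j <- match(tm, coefs[[i]]$term)
      if (!is.na(j)) {
        has[i] <- TRUE
        est[i] <- coefs[[i]]$estimate[j]
        se[i] <- coefs[[i]]$std.error[j]
      }
    }
    ws <- sum(w[has])
    wc <- w[has] / ws
    b_cond <- sum(wc * est[has])
    se_cond <- sum(wc * sqrt(se[has]^2 + (est[has] - b_cond)^2))
    b_full <- sum(w * est)
    se_full <- sum(w * sqrt(se^2 + (est - b_full)^2))
    tibble::tibble(term = tm, weight_sum = ws,
                   estimate_cond = b_cond, se_cond = se_cond,
                   conf.low_cond = b_cond - 1.96 * se_cond,
                   conf.high_cond = b_cond + 1.96 * se_cond,
                   estimate_full = b_full, se_full = se_full,
                   conf.low_full = b_full - 1.96 * se_full,
                   conf.high_full = b_full + 1.96 * se_full)
  })
  dplyr::bind_rows(rows)
}

#' Generalized variance inflation factors
#'
#' Collinearity diagnostics on the predictor set, with the dimensionality
#' correction for multi-level predictors: `GVIF^(1/(2 df))`, `df` being
#' the number of indicator columns the predictor expands to (categories
#' minus one). The square of the corrected value is interpretable on the
#' ordinary VIF scale (< 2 no collinearity, > 5 high collinearity). GVIF
#' is computed from determinants of the predictor correlation matrix
#' (intercept excluded): `det(R11) det(R22) / det(R)`.
#'
#' @param data Prepared trait table.
#' @param specs List of [predictor_spec()]s (at least two).
#' @return A tibble: `predictor`, `gvif`, `df`, `gvif_corrected`
#'   (`gvif^(1/(2 df))`), `interpretation` (band applied to the corrected
#'   value squared).
#' @export
gvif <- function(data, specs) {
  nm <- vapply(specs, `[[`, "", "name")
  if (length(nm) < 2) stop("GVIF needs at least two predictors", call. = FALSE)
  f <- stats::as.formula(paste("~", paste(nm, collapse = " + ")))
  X <- stats::model.matrix(f, as.data.frame(data))[, -1, drop = FALSE]
  assign <- attr(stats::model.matrix(f, as.data.frame(data)), "assign")[-1]
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant columns in design: ",
         paste(colnames(X)[apply(X, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  }
  R <- stats::cor(X)
  detR <- det(R)
  if (abs(detR) < 1e-12) {
    stop("singular predictor correlation matrix; aliased columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(nm), function(i) {
    g <- which(assign == i)
    df <- length(g)
    g_v <- det(R[g, g, drop = FALSE]) *
      det(R[-g, -g, drop = FALSE]) / detR
    corrected <- g_v^(1 / (2 * df))
    band <- if (corrected^2 < 2) "none" else if (corrected^2 <= 5)
      "moderate" else "high"
    tibble::tibble(predictor = nm[i], gvif = g_v, df = df,
                   gvif_corrected = corrected, interpretation = band)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.model_set <- function(x, ...) {
  cat("PGLS model set:", nrow(x$table), "models, best:",
      x$table$model[1], "\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Tidy a model set (the ranked model table)
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return The ranked tibble.
#' @exportS3Method generics::tidy
tidy.model_set <- function(x, ...) x$table

#' One-row summary of a model set
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return A tibble: `n_models`, `best_model`, `best_AICc`,
#'   `best_r.squared`, `best_lambda`, `n_conf_set` (95% set size).
#' @exportS3Method generics::glance
glance.model_set <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$table),
                 best_model = x$table$model[1],
                 best_AICc = x$table$AICc[1],
                 best_r.squared = x$table$r.squared[1],
                 best_lambda = x$table$lambda[1],
                 n_conf_set = nrow(confidence_set(x)))
}
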