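#' Single-predictor PGLS table
#'
#' Fits one PGLS model per declared predictor (plus the intercept-only
#' null), each with lambda estimated by maximum likelihood, and assembles
#' the standard comparison table: coefficient and standard error for
#' continuous predictors, overall likelihood-ratio significance against
#' the null for categorical ones, per-model lambda, log-likelihood, AICc
#' difference to the best model, Akaike weight, and R-squared against the
#' same-lambda null.
#'
#' @param data Prepared trait table (see [prepare_predictors()]).
#' @param tree Phylogeny or covariance matrix.
#' @param response Response column name.
#' @param specs List of [predictor_spec()]s.
#' @param taxa Taxon column name.
#' @return A tibble with one row per model (the intercept-only model is
#'   labeled `"1"`), ordered by AICc: `model`, `intercept`,
#'   `coefficient`, `std.error`, `p.value`, `df` (number of fixed-effect
#'   coefficients), `lambda`, `logLik`, `AICc`, `delta_AICc`, `weight`,
#'   `r.squared`.
#' @export
single_predictor_table <- function(data, tree, response, specs,
                                   taxa = "species") {
  C <- if (is.matrix(tree)) tree else
    phylo_covariance(tree, order = as.character(data[[taxa]]))
  null_fit <- pgls(stats::as.formula(paste(response, "~ 1")), data, C,
                   taxa = taxa)
  rows <- list(tibble::tibble(
    model = "1", intercept = unname(coef(null_fit)[1]),
    coefficient = NA_real_, std.error = NA_real_, p.value = NA_real_,
    df = 1L, lambda = null_fit$lambda, logLik = null_fit$logLik,
    AICc = null_fit$AICc, r.squared = 0))
  for (s in specs) {
    f <- stats::as.formula(paste(response, "~", s$name))
    fit <- pgls(f, data, C, taxa = taxa)
    td <- tidy(fit)
    if (s$role == "categorical") {
      lr <- max(0, 2 * (fit$logLik - null_fit$logLik))
      p <- stats::pchisq(lr, df = nrow(td) - 1, lower.tail = FALSE)
      co <- se <- NA_real_
    } else {
      co <- td$estimate[2]; se <- td$std.error[2]; p <- td$p.value[2]
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      model = s$name, intercept = td$estimate[1], coefficient = co,
      std.error = se, p.value = p, df = nrow(td), lambda = fit$lambda,
      logLik = fit$logLik, AICc = fit$AICc, r.squared = fit$r_squared)
  }
  tab <- dplyr::bind_rows(rows)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  tab |>
    dplyr::arrange(.data$AICc) |>
    dplyr::relocate("delta_AICc", "weight", .after = "AICc")
}

read_table_arg <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  tibble::as_tibble(utils::read.csv(x, stringsAsFactors = FALSE)) |>
    dplyr::mutate(dplyr::across(dplyr::any_of(c("band_date", "rec_date")),
                                as.Date))
}

#' Pipeline configuration
#'
#' @param records,meta,wings,tree Input tables (data frames or CSV
#'   paths; `tree` a phylogeny object or Newick path). `wings` may be
#'   `NULL` when an `aspect_ratio` column is supplied via `traits`.
#' @param traits Optional extra per-species predictor table joined by
#'   `species`.
#' @param specs List of [predictor_spec()]s for the multi-model stage.
#' @param out_dir Output directory.
#' @param min_n Minimum records per retained species (default 5).
#' @param filter A [filter_config()].
#' @param max_terms,interactions Passed to [enumerate_models()].
#' @param level Confidence-set level (default 0.95).
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(records, meta, tree, wings = NULL,
                            traits = NULL, specs = list(),
                            out_dir = tempfile("natdisp-run-"),
                            min_n = 5, filter = filter_config(),
                            max_terms = 5, interactions = TRUE,
                            level = 0.95, seed = 1L) {
  structure(list(records = records, meta = meta, tree = tree,
                 wings = wings, traits = traits, specs = specs,
                 out_dir = out_dir, min_n = min_n, filter = filter,
                 max_terms = max_terms, interactions = interactions,
                 level = level, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full natal-dispersal analysis pipeline
#'
#' records + metadata (+ wings + tree) to dispersal estimates, merged
#' trait table, single-predictor comparison table, and all-subsets
#' multimodel outputs (ranked models, confidence set, variable
#' importance, model-averaged coefficients, GVIF). Every stage's tabular
#' output is written as CSV under `config$out_dir`, the filter audit as
#' JSON, and a manifest records the seed and a hash of the configuration
#' and inputs; outputs are deterministic, so reruns on identical inputs
#' are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`estimates`,
#'   `audit`, `trait_table`, `single_predictor`, `model_set`,
#'   `importance`, `averaged`, `gvif`, `signal`, `manifest`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- run_stage("read-records", read_table_arg(config$records))
  meta <- run_stage("read-meta", read_table_arg(config$meta))
  tree <- run_stage("read-tree", read_phylogeny(config$tree))

  pre_missing <- setdiff(unique(records$species), tree$tip.label)
  if (length(pre_missing)) {
    stop("pipeline stage 'pre-flight' failed: species absent from tree: ",
         paste(pre_missing, collapse = ", "), call. = FALSE)
  }

  filtered <- run_stage("filter", filter_records(records, meta, config$filter))
  audit <- filter_audit(filtered)
  estimates <- run_stage("estimate",
                         estimate_dispersal(filtered) |>
                           retain_species(config$min_n))

  trait_table <- estimates |>
    dplyr::mutate(log_dispersal = log(.data$geomean_km)) |>
    dplyr::left_join(dplyr::select(meta, -dplyr::any_of(
      c("season_start_month", "season_end_month", "lat_min", "lat_max",
        "lon_min", "lon_max"))), by = "species")
  if (!is.null(config$wings)) {
    ar <- run_stage("aspect-ratio",
                    species_aspect_ratio(read_table_arg(config$wings)))
    trait_table <- dplyr::left_join(
      trait_table,
      dplyr::select(ar, "species", aspect_ratio = "mean_AR"),
      by = "species")
  }
  if (!is.null(config$traits)) {
    trait_table <- dplyr::left_join(trait_table,
                                    read_table_arg(config$traits),
                                    by = "species")
  }

  results <- list(estimates = estimates, audit = audit,
                  trait_table = trait_table)

  if (length(config$specs)) {
    prepared <- run_stage("prepare",
      prepare_predictors(trait_table, config$specs,
                         response = "log_dispersal"))
    dropped <- attr(prepared, "dropped")
    if (nrow(dropped)) {
      message("dropped ", nrow(dropped),
              " species with missing predictors: ",
              paste(dropped$species, collapse = ", "))
    }
    results$signal <- run_stage("signal",
      phylo_signal(prepared, tree, taxa = "species",
                   value = "log_dispersal"))
    results$single_predictor <- run_stage("single-predictor",
      single_predictor_table(prepared, tree, "log_dispersal", config$specs))
    results$model_set <- run_stage("dredge",
      fit_model_set(prepared, tree, "log_dispersal", config$specs,
                    max_terms = config$max_terms,
                    interactions = config$interactions))
    results$confidence_set <- confidence_set(results$model_set,
                                             config$level)
    results$importance <- variable_importance(results$model_set)
    results$averaged <- model_average(results$model_set)
    results$gvif <- if (length(config$specs) >= 2)
      run_stage("gvif", gvif(prepared, config$specs)) else NULL
  }

  manifest <- list(
    package = "natdisp",
    version = as.character(utils::packageVersion("natdisp")),
    seed = config$seed,
    n_records_in = nrow(records),
    n_species_retained = nrow(estimates),
    config_hash = rlang::hash(list(records, meta,
                                   ape::write.tree(tree),
                                   config[setdiff(names(config),
                                                  c("records", "meta",
                                                    "tree", "out_dir"))]))
  )
  results$manifest <- manifest

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(
    x, file.path(config$out_dir, f), row.names = FALSE)
  wcsv(dplyr::mutate(estimates,
                     geomean_km = round(.data$geomean_km, 1)),
       "dispersal_estimates.csv")
  jsonlite::write_json(audit, file.path(config$out_dir,
                                        "filter_audit.json"),
                       auto_unbox = TRUE, digits = NA)
  wcsv(trait_table, "trait_table.csv")
  if (!is.null(results$single_predictor))
    wcsv(results$single_predictor, "single_predictor_table.csv")
  if (!is.null(results$model_set)) {
    wcsv(results$model_set$table, "model_table.csv")
    wcsv(results$confidence_set, "confidence_set.csv")
    wcsv(results$importance, "importance.csv")
    wcsv(results$averaged, "averaged_coefficients.csv")
    if (!is.null(results$gvif)) wcsv(results$gvif, "gvif.csv")
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Reproduce the published comparative analysis from deposited data
#'
#' Runs the exact analysis stack — single-predictor table, phylogenetic
#' signal, all-subsets multimodel inference — on a per-species trait
#' table and tree as deposited in a data archive (species, geometric-mean
#' dispersal distance in km, wing aspect ratio, population size, mass,
#' migration distance, range area, mean recovery years, habitat, diet,
#' foraging, migratory). Continuous predictors are log-transformed and
#' standardized; habitat uses the coast reference level.
#'
#' @param traits Per-species table with (a subset of) the columns above;
#'   must include `species` and `dispersal_km`.
#' @param tree Phylogeny covering the species.
#' @param max_terms Cap on variables per model (default 5).
#' @return A list: `single_predictor`, `signal`, `model_set`,
#'   `confidence_set`, `importance`, `averaged`, `gvif`.
#' @export
reproduce_benchmark <- function(traits, tree, max_terms = 5) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("species", "dispersal_km") %in% names(traits)))
  traits$log_dispersal <- log(traits$dispersal_km)
  spec_pool <- list(
    predictor_spec("aspect_ratio", "continuous", log_transform = TRUE),
    predictor_spec("recovery_years", "continuous", log_transform = TRUE),
    predictor_spec("population_size", "continuous", log_transform = TRUE),
    predictor_spec("mass", "continuous", log_transform = TRUE),
    predictor_spec("migration_distance", "continuous", log_transform = TRUE),
    predictor_spec("range_area", "continuous", log_transform = TRUE),
    predictor_spec("habitat", "categorical", reference = "coast"),
    predictor_spec("diet", "categorical"),
    predictor_spec("foraging", "categorical"),
    predictor_spec("migratory", "binary")
  )
  specs <- Filter(function(s) s$name %in% names(traits), spec_pool)
  prepared <- prepare_predictors(traits, specs, response = "log_dispersal")
  ms <- fit_model_set(prepared, tree, "log_dispersal", specs,
                      max_terms = max_terms)
  list(single_predictor = single_predictor_table(prepared, tree,
                                                 "log_dispersal", specs),
       signal = phylo_signal(prepared, tree, value = "log_dispersal"),
       model_set = ms,
       confidence_set = confidence_set(ms),
       importance = variable_importance(ms),
       averaged = model_average(ms),
       gvif = gvif(prepared, specs))
}
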