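#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot for a PGLS fit
#'
#' Observed against fitted values with the identity line; a quick check
#' of fit quality and outlying taxa.
#'
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pgls_fit <- function(object, ...) {
  df <- tibble::tibble(fitted = object$fitted, observed = object$response,
                       taxon = object$taxa)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Fitted", y = "Observed",
      title = sprintf("PGLS fit (lambda = %.2f, R2 = %.2f)",
                      object$lambda, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a ranked model set
#'
#' Akaike weights of the top models (default 15), annotated with the
#' cumulative weight, the usual view of model-selection uncertainty.
#'
#' @param object A `model_set`.
#' @param n_models Number of top models to show.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.model_set <- function(object, n_models = 15, ...) {
  tab <- utils::head(object$table, n_models)
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL,
                  title = "Top models by AICc") +
    ggplot2::theme_minimal()
}

#' Plot variable importance
#'
#' @param importance Output of [variable_importance()].
#' @return A ggplot of importance (summed Akaike weights) per predictor.
#' @export
plot_importance <- function(importance) {
  importance$variable <- factor(importance$variable,
                                levels = rev(importance$variable))
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = .data$importance, y = .data$variable)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Importance (sum of model probabilities)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Audit map of banding-to-recovery displacements
#'
#' Simple segment plot of banding and recovery points (one segment per
#' record) for visual inspection of the filtered data; not a projected
#' map.
#'
#' @param records Record table (see [filter_records()]).
#' @return A ggplot.
#' @export
plot_records_map <- function(records) {
  ggplot2::ggplot(records) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$band_lon, y = .data$band_lat,
                   xend = .data$rec_lon, yend = .data$rec_lat,
                   color = .data$species),
      alpha = 0.4, show.legend = FALSE) +
    ggplot2::geom_point(ggplot2::aes(x = .data$band_lon,
                                     y = .data$band_lat), size = 0.3) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = "Banding-to-recovery displacements") +
    ggplot2::theme_minimal()
}
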