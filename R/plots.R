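# ggplot2 autoplot methods for the main result types.

#' Plot an affordance histogram
#'
#' Raw bin mass as bars with the smoothed histogram overlaid, the standard
#' presentation of angular navigability data.
#'
#' @param object an [affordance_histogram()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.affordance_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_deg)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$raw), fill = "grey65", width = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::labs(x = "direction (degrees; 90 = straight ahead)",
                  y = "navigability mass") +
    ggplot2::theme_minimal()
}

#' Plot an RDM as a heat map
#'
#' @param object an [rdm()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rdm <- function(object, ...) {
  m <- as.matrix(object)
  df <- tidyr::expand_grid(row = rownames(m), col = colnames(m))
  df$dissimilarity <- as.vector(t(m))
  df$row <- factor(df$row, levels = rev(rownames(m)))
  df$col <- factor(df$col, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = attr(object, "source") %||% NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a slice-occlusion shared-variance profile
#'
#' Per-row shared variance for each layer and target; image rows run from
#' top (left) to bottom (right) of the axis.
#'
#' @param object a `slice_experiment`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.slice_experiment <- function(object, ...) {
  ggplot2::ggplot(object$pixel_profile,
                  ggplot2::aes(.data$row, .data$shared_variance_pct,
                               color = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = "image row (top to bottom)", y = "shared variance (%)") +
    ggplot2::theme_minimal()
}

#' Plot a unit-resampling null distribution
#'
#' Kernel density of the null accuracies with the focal subset's accuracy
#' marked.
#'
#' @param object a `resampling_null`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.resampling_null <- function(object, ...) {
  df <- tidy.resampling_null(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_density(fill = "grey80", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$focal_accuracy,
                        color = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "accuracy (%)", y = "density",
                  subtitle = sprintf("focal subset at the %.0fth percentile",
                                     object$percentile)) +
    ggplot2::theme_minimal()
}

#' Plot a unit embedding with cluster assignments
#'
#' @param object a `unit_embedding`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.unit_embedding <- function(object, ...) {
  ggplot2::ggplot(object$embedding,
                  ggplot2::aes(.data$x, .data$y,
                               color = factor(.data$cluster))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "embedding dim 1", y = "embedding dim 2",
                  color = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot feature-experiment shared variance
#'
#' Mean shared variance across layers per filter and target, with SEM error
#' bars.
#'
#' @param object a `feature_experiment`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.feature_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$filter, .data$mean_sv)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_sv - .data$sem_sv,
                                        ymax = .data$mean_sv + .data$sem_sv),
                           width = 0.2) +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = NULL, y = "shared variance (%)") +
    ggplot2::theme_minimal()
}
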