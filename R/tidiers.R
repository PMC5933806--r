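# broom-style tidiers for the package's result objects.

#' Tidy a commonality result
#'
#' @param x a `commonality_result`.
#' @param ... unused.
#' @return One row per variance component plus the shared-variance
#'   percentage.
#' @export
tidy.commonality_result <- function(x, ...) {
  tibble::tibble(
    component = c("r2_full", "r2_x1", "r2_x2", "gamma1", "gamma2",
                  "gamma12", "shared_variance_pct"),
    value = c(x$r2_full, x$r2_x1, x$r2_x2, x$gamma1, x$gamma2, x$gamma12,
              x$shared_variance_pct)
  )
}

#' @rdname tidy.commonality_result
#' @export
glance.commonality_result <- function(x, ...) {
  tibble::tibble(r2_full = x$r2_full,
                 shared_variance_pct = x$shared_variance_pct,
                 sv_defined = x$sv_defined)
}

#' Tidy an RSA comparison
#'
#' @param x an `rsa_result` from [rsa_compare()].
#' @param ... unused.
#' @return One-row tibble with the statistic and its inference record.
#' @export
tidy.rsa_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, bootstrap_se = x$bootstrap_se,
                 p_value = x$p_value, p_corrected = x$p_corrected,
                 n_iterations = x$n_iterations,
                 resample_fraction = x$resample_fraction)
}

#' Tidy a regression RSA fit
#'
#' @param x a `regression_rsa`.
#' @param ... unused.
#' @return One row per coefficient.
#' @export
tidy.regression_rsa <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.regression_rsa
#' @export
glance.regression_rsa <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_pairs = x$n_pairs)
}

#' Tidy a classification result
#'
#' @param x a `classification_result`.
#' @param ... unused.
#' @return Per-image predictions.
#' @export
tidy.classification_result <- function(x, ...) x$predictions

#' @rdname tidy.classification_result
#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, accuracy = x$accuracy,
                 n_images = x$n_images, n_correct = x$n_correct)
}

#' Tidy a unit-resampling null
#'
#' @param x a `resampling_null`.
#' @param ... unused.
#' @return One row per null draw.
#' @export
tidy.resampling_null <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$null_accuracies),
                 accuracy = x$null_accuracies)
}

#' @rdname tidy.resampling_null
#' @export
glance.resampling_null <- function(x, ...) {
  tibble::tibble(focal_accuracy = x$focal_accuracy,
                 percentile = x$percentile,
                 n_iterations = x$n_iterations)
}

#' Tidy a noise ceiling
#'
#' @param x a `noise_ceiling`.
#' @param ... unused.
#' @return One row per subject.
#' @export
tidy.noise_ceiling <- function(x, ...) {
  tibble::tibble(subject = seq_along(x$per_subject),
                 correlation = x$per_subject)
}

#' Summarize a pipeline run as one row
#'
#' @param x a `navrsa_pipeline` from [run_pipeline()].
#' @param ... unused.
#' @return One-row tibble of the pipeline's headline quantities.
#' @export
glance.navrsa_pipeline <- function(x, ...) {
  s <- x$summary
  tibble::as_tibble(s[vapply(s, is.numeric, logical(1))]) |>
    dplyr::mutate(best_layer = s$best_layer, .before = 1)
}
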