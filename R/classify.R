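#' Minimum-distance classification of binary scene properties
#'
#' Unit activations are z-scored across images, then z-scored across units;
#' an image x image Euclidean distance matrix is computed from the doubly
#' normalized activations, and each image is assigned to the class ("low" or
#' "high") with the smaller mean pairwise distance, excluding the comparison
#' of the image to itself. Ties go to the lexicographically first class
#' label (with a message). This classifier has no fitted parameters, which
#' suits activation sets with far more units than images.
#'
#' @param activations image x unit matrix (or a `labeled_activations`).
#' @param labels two-level factor over images (defaults to the focal
#'   property of a `labeled_activations`).
#' @param units optional unit subset.
#' @return A `classification_result`: list with `accuracy` (percent
#'   correct), `n_images`, `n_correct`, `classifier`, `predictions` tibble.
#' @export
min_distance_classify <- function(activations, labels = NULL, units = NULL) {
  al <- resolve_activations(activations, labels, units)
  X <- al$X; y <- al$y
  classes <- levels(y)
  abort_if(min(table(y)) < 2, "each class needs at least two members")
  X <- zscore_cols(X, drop = TRUE)
  X <- zscore_rows(X)
  D <- as.matrix(dist(X))
  n <- nrow(X)
  pred <- character(n); tie <- FALSE
  for (i in seq_len(n)) {
    md <- vapply(classes, function(cl) {
      others <- which(y == cl & seq_len(n) != i)
      mean(D[i, others])
    }, numeric(1))
    if (abs(md[1] - md[2]) < 1e-15) {
      tie <- TRUE
      pred[i] <- sort(classes)[1]
    } else {
      pred[i] <- classes[which.min(md)]
    }
  }
  if (tie) message("min_distance_classify: distance tie(s) broken toward '",
                   sort(classes)[1], "'")
  classification_result(y, factor(pred, levels = classes), "min_distance")
}

resolve_activations <- function(activations, labels, units) {
  if (inherits(activations, "labeled_activations")) {
    if (is.null(labels)) labels <- activations$labels[[1]]
    activations <- activations$activations
  }
  abort_if(is.null(labels), "labels are required")
  y <- droplevels(as.factor(labels))
  abort_if(nlevels(y) != 2, "labels must have exactly two classes")
  X <- as.matrix(activations)
  if (!is.null(units)) X <- X[, units, drop = FALSE]
  abort_if(nrow(X) != length(y), "labels must match the image count")
  list(X = X, y = y)
}

classification_result <- function(y, pred, classifier, extra = list()) {
  correct <- pred == y
  structure(c(list(
    accuracy = 100 * mean(correct),
    n_images = length(y),
    n_correct = sum(correct),
    classifier = classifier,
    predictions = tibble::tibble(truth = y, predicted = pred,
                                 correct = correct)
  ), extra), class = "classification_result")
}

# Ledoit-Wolf shrinkage intensity toward the scaled identity, computed from
# class-centered residuals.
lw_shrinkage <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < 1e-300) return(0)
  b2 <- (sum(rowSums(Xc^2)^2) / n^2 - sum(S^2) / n) / p
  max(0, min(1, b2 / d2))
}

#' Leave-one-out linear discriminant classification
#'
#' For each held-out image a two-class linear discriminant is fit on the
#' remaining images -- pooled covariance regularized by Ledoit-Wolf-style
#' shrinkage toward the scaled identity, equal class priors (the design is
#' balanced, and training-proportion priors would systematically vote
#' against every held-out image, whose own class is always the training
#' minority) -- and the held-out image is predicted; accuracy is the
#' percentage of correct predictions across all images. The shrinkage
#' intensity is estimated once
#' from the full data of the unit subset and reused across folds, whose
#' means and scatters are updated by exact sufficient-statistic downdates.
#'
#' @param activations image x unit matrix (or `labeled_activations`).
#' @param labels two-level factor (defaults to the focal property).
#' @param units optional unit subset (e.g. a selected 50-unit subset).
#' @return A `classification_result` with `classifier =
#'   "linear_discriminant"` and the `shrinkage` intensity used.
#' @export
loo_lda_classify <- function(activations, labels = NULL, units = NULL) {
  al <- resolve_activations(activations, labels, units)
  X <- al$X; y <- al$y
  n <- nrow(X); p <- ncol(X)
  abort_if(n < 4, "need at least 4 images")
  classes <- levels(y)
  idx1 <- y == classes[1]; idx2 <- y == classes[2]
  n1 <- sum(idx1); n2 <- sum(idx2)
  abort_if(min(n1, n2) < 2, "each class needs at least two members")

  # Full-data sufficient statistics.
  s1 <- colSums(X[idx1, , drop = FALSE]); s2 <- colSums(X[idx2, , drop = FALSE])
  C1 <- crossprod(X[idx1, , drop = FALSE]); C2 <- crossprod(X[idx2, , drop = FALSE])
  Xc <- X
  Xc[idx1, ] <- sweep(X[idx1, , drop = FALSE], 2, s1 / n1)
  Xc[idx2, ] <- sweep(X[idx2, , drop = FALSE], 2, s2 / n2)
  lambda <- lw_shrinkage(Xc)

  pred <- character(n)
  for (i in seq_len(n)) {
    in1 <- idx1[i]
    m1 <- n1 - in1; m2 <- n2 - (!in1)
    t1 <- s1 - if (in1) X[i, ] else 0
    t2 <- s2 - if (in1) 0 else X[i, ]
    G1 <- C1 - if (in1) tcrossprod(X[i, ]) else 0
    G2 <- C2 - if (in1) 0 else tcrossprod(X[i, ])
    mu1 <- t1 / m1; mu2 <- t2 / m2
    scatter <- (G1 - m1 * tcrossprod(mu1)) + (G2 - m2 * tcrossprod(mu2))
    Sigma <- scatter / (m1 + m2 - 2)
    tr_mean <- sum(diag(Sigma)) / p
    Sigma <- (1 - lambda) * Sigma + diag(lambda * tr_mean, p)
    wv <- tryCatch(solve(Sigma, mu2 - mu1), error = function(e) {
      # near-singular even after estimated shrinkage: fall back to a
      # stronger ridge and note it
      message("loo_lda_classify: singular covariance; extra shrinkage engaged")
      solve(Sigma + diag(1e-6 * max(tr_mean, 1), p), mu2 - mu1)
    })
    score <- sum(wv * (X[i, ] - (mu1 + mu2) / 2))
    pred[i] <- if (score > 0) classes[2] else classes[1]
  }
  classification_result(y, factor(pred, levels = classes),
                        "linear_discriminant",
                        extra = list(shrinkage = lambda))
}

#' Unit-resampling null for a focal unit subset
#'
#' Quantifies how informative a designated unit subset is relative to
#' equally sized random subsets of the same layer: the classification
#' accuracy of the focal subset is compared with the accuracies of
#' `n_iterations` random subsets of the same size, drawn without excluding
#' the focal units. The percentile is the strictly-less rank
#' `100 * (# null < focal) / n_iterations`.
#'
#' @param activations image x unit matrix (or `labeled_activations`).
#' @param focal_units indices of the focal subset.
#' @param labels two-level factor (defaults to the focal property).
#' @param n_iterations number of random subsets.
#' @param seed integer seed.
#' @param classifier classification function (default [loo_lda_classify()]).
#' @return A `resampling_null`: list with `focal_accuracy`,
#'   `null_accuracies`, `percentile`, `n_iterations`, `seed`.
#' @export
resampling_null <- function(activations, focal_units, labels = NULL,
                            n_iterations = 5000, seed = 0L,
                            classifier = loo_lda_classify) {
  al <- resolve_activations(activations, labels, NULL)
  n_units <- ncol(al$X)
  abort_if(length(focal_units) > n_units, "focal subset larger than the layer")
  focal <- classifier(al$X, al$y, units = focal_units)$accuracy
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      classifier(al$X, al$y, units = sample(n_units, length(focal_units)))$accuracy
    }, numeric(1))
  })
  structure(list(focal_accuracy = focal, null_accuracies = nulls,
                 percentile = 100 * sum(nulls < focal) / n_iterations,
                 n_iterations = n_iterations, seed = as.integer(seed)),
            class = "resampling_null")
}

#' Chi-squared comparison of two classification accuracies
#'
#' A 2x2 chi-squared test for equality of proportions on the
#' correct/incorrect counts of two classification results, optionally
#' Bonferroni-corrected for a family of property comparisons. Expected cell
#' counts below 1 are flagged with a warning.
#'
#' @param result_a,result_b `classification_result`s over the same fold
#'   scheme.
#' @param m_comparisons Bonferroni comparison count.
#' @return Tibble with the statistic, `p_value` and `p_corrected`.
#' @export
compare_accuracies <- function(result_a, result_b, m_comparisons = 1) {
  k <- c(result_a$n_correct, result_b$n_correct)
  n <- c(result_a$n_images, result_b$n_images)
  expected <- outer(c(sum(k), sum(n) - sum(k)), n / sum(n))
  if (min(expected) < 1) warning("expected cell count below 1; ",
                                 "chi-squared approximation is unreliable")
  if (result_a$n_correct == result_b$n_correct &&
      result_a$n_images == result_b$n_images) {
    stat <- 0; p <- 1
  } else {
    ht <- suppressWarnings(prop.test(k, n, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  tibble::tibble(statistic = stat, p_value = p,
                 p_corrected = unname(bonferroni(p, m_comparisons)),
                 accuracy_a = result_a$accuracy, accuracy_b = result_b$accuracy)
}
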