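#' Representational dissimilarity matrices
#'
#' An RDM is a symmetric, zero-diagonal, nonnegative condition x condition
#' matrix of squared Euclidean dissimilarities with unique condition labels.
#' Squared Euclidean distances are used throughout because they sum linearly,
#' which multiple-regression RSA and commonality analysis require; on
#' z-scored patterns they are linearly proportional to Pearson correlation
#' distances (see [compute_rdm()]).
#'
#' @param values square numeric matrix.
#' @param labels condition labels (default: rownames, else `cond1..n`).
#' @param source free-text provenance.
#' @return An object of class `rdm` (a labelled matrix).
#' @export
rdm <- function(values, labels = NULL, source = "") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(labels)) labels <- rownames(values) %||% paste0("cond", seq_len(n))
  abort_if(length(labels) != n, "labels must match matrix dimension")
  abort_if(anyDuplicated(labels) > 0, "condition labels must be unique")
  values <- validate_rdm(values)
  dimnames(values) <- list(labels, labels)
  structure(values, source = source, class = c("rdm", class(values)))
}

validate_rdm <- function(x, tol = 1e-8) {
  x <- unclass(as.matrix(x))
  abort_if(nrow(x) != ncol(x), "RDM must be square")
  abort_if(!all(is.finite(x)), "RDM must be finite")
  abort_if(max(abs(x - t(x))) > tol * max(1, max(abs(x))), "RDM must be symmetric")
  abort_if(max(abs(diag(x))) > tol * max(1, max(abs(x))), "RDM diagonal must be zero")
  abort_if(min(x) < -tol * max(1, max(abs(x))), "RDM entries must be nonnegative")
  x <- (x + t(x)) / 2
  diag(x) <- 0
  x[x < 0] <- 0
  x
}

#' Condition labels of an RDM
#'
#' @param x an [rdm()] or labelled square matrix.
#' @return Character vector of condition labels.
#' @export
rdm_labels <- function(x) rownames(x) %||% paste0("cond", seq_len(nrow(x)))

#' Vectorize an RDM
#'
#' Extracts the off-diagonal upper triangle, the single vector
#' representation used by all inference operations (diagonal elements are
#' never used). Length is `n * (n - 1) / 2`.
#'
#' @param x an [rdm()] or symmetric matrix.
#' @return Numeric vector of pairwise dissimilarities.
#' @export
rdm_vec <- function(x) {
  x <- as.matrix(x)
  x[upper.tri(x)]
}

#' Subset an RDM to a condition subset
#'
#' @param x an [rdm()].
#' @param idx condition indices (or labels).
#' @return The sub-RDM.
#' @export
rdm_subset <- function(x, idx) {
  m <- as.matrix(x)[idx, idx, drop = FALSE]
  rdm(m, source = attr(x, "source") %||% "")
}

#' Normalize multi-run voxel patterns
#'
#' The normalization chain for condition-rich fMRI response patterns: each
#' voxel is z-scored across conditions within each run, runs are averaged,
#' and each condition's response pattern is then z-scored across voxels.
#' Voxels with zero variance within any run are excluded (not imputed) from
#' all runs, with a message reporting the count.
#'
#' @param runs list of condition x voxel matrices with identical dimensions
#'   and condition order.
#' @return Condition x voxel matrix of doubly normalized patterns, with
#'   attribute `dropped_voxels`.
#' @export
normalize_fmri <- function(runs) {
  abort_if(length(runs) < 1, "at least one run is required")
  dims <- vapply(runs, dim, integer(2))
  abort_if(any(dims != dims[, 1]), "all runs must have identical dimensions")
  rn <- lapply(runs, rownames)
  abort_if(!all(vapply(rn, identical, logical(1), rn[[1]])),
           "condition order must be identical across runs")
  sds <- sapply(runs, function(r) apply(r, 2, sd))
  sds <- matrix(sds, ncol = length(runs))
  dead <- apply(sds < 1e-12, 1, any)
  if (any(dead)) {
    message("normalize_fmri: excluding ", sum(dead),
            " zero-variance voxel(s)")
    runs <- lapply(runs, function(r) r[, !dead, drop = FALSE])
  }
  zruns <- lapply(runs, function(r) zscore_cols(r))
  avg <- Reduce(`+`, zruns) / length(zruns)
  out <- zscore_rows(avg)
  attr(out, "dropped_voxels") <- sum(dead)
  out
}

#' Reduce activation patterns with PCA
#'
#' PCA is fitted over conditions with per-feature mean centering only (no
#' feature standardization); the top-`k` component scores are retained and,
#' by default, each condition's score vector is z-scored across components --
#' the convention used before computing network RDMs.
#'
#' @param x condition x feature matrix.
#' @param k number of components; must not exceed
#'   `min(n_conditions - 1, n_features)`.
#' @param zscore z-score each condition's scores across components
#'   (default `TRUE`).
#' @return Condition x component score matrix.
#' @export
reduce_pca <- function(x, k, zscore = TRUE) {
  x <- as.matrix(x)
  avail <- min(nrow(x) - 1, ncol(x))
  abort_if(k > avail, "k = ", k, " exceeds the available rank (", avail, ")")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- p$x[, seq_len(k), drop = FALSE]
  if (zscore) scores <- zscore_rows(scores)
  rownames(scores) <- rownames(x)
  scores
}

#' Compute a squared-Euclidean RDM from patterns
#'
#' `d(i, j) = sum_f (x_if - x_jf)^2`. When the rows of `x` are z-scored
#' across features with the sample (n - 1) denominator, the identity
#' `d = 2 * (n_features - 1) * (1 - r)` holds exactly, with `r` the Pearson
#' correlation between patterns.
#'
#' @param x condition x feature matrix (no non-finite entries).
#' @param labels condition labels (default: rownames).
#' @param source provenance string.
#' @return An [rdm()].
#' @export
compute_rdm <- function(x, labels = NULL, source = "") {
  x <- as.matrix(x)
  abort_if(!all(is.finite(x)), "patterns contain non-finite values")
  d <- as.matrix(dist(x))^2
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  rdm(d, source = source)
}

#' Average subject-level RDMs into a group RDM
#'
#' @param subject_rdms list of [rdm()]s sharing labels and label order.
#' @return The elementwise mean as an [rdm()].
#' @export
group_rdm <- function(subject_rdms) {
  abort_if(length(subject_rdms) < 1, "need at least one RDM")
  labs <- lapply(subject_rdms, rdm_labels)
  abort_if(!all(vapply(labs, identical, logical(1), labs[[1]])),
           "subject RDMs must share labels and label order")
  m <- Reduce(`+`, lapply(subject_rdms, as.matrix)) / length(subject_rdms)
  rdm(m, labels = labs[[1]], source = "group mean")
}

#' Write / read an RDM as square CSV
#'
#' @param x an [rdm()].
#' @param path CSV path.
#' @return `path` (write) or an [rdm()] (read).
#' @export
write_rdm_csv <- function(x, path) {
  write.csv(as.data.frame(as.matrix(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  rdm(as.matrix(df))
}
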