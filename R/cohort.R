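#' Generate a multi-subject, multi-run voxel-pattern cohort with planted
#' representational geometry
#'
#' Builds noiseless base patterns whose squared-Euclidean RDM equals
#' `target_rdm` exactly, then adds i.i.d. Gaussian run-level noise. The base
#' construction is: classical multidimensional-scaling embedding of the
#' target RDM (top nonnegative eigenvalues; eigenvalues below `1e-10 *` the
#' maximum are truncated as numerical rank), followed by a distance-preserving
#' map into voxel space through an equal-column-norm frame with a mirrored
#' sign structure. The frame makes every voxel's variance across conditions
#' identical and every condition's mean across voxels zero, so the planted
#' geometry is also invariant to per-voxel gain normalization.
#'
#' @param target_rdm an [rdm()] (symmetric, zero diagonal, nonnegative) that
#'   is Euclidean-embeddable: the double-centered `-D/2` matrix must be
#'   positive semidefinite up to numerical tolerance.
#' @param n_subjects,n_runs cohort dimensions.
#' @param n_voxels number of voxels; must be at least twice the embedding
#'   rank of `target_rdm` (the mirrored frame needs paired voxels).
#' @param noise_sd SD of additive Gaussian noise per run.
#' @param seed integer seed.
#' @return A `synthetic_cohort`: list with `patterns` (per subject, a list of
#'   per-run condition x voxel matrices), `base` (noiseless patterns),
#'   `target_rdm`, `noise_sd` and `seed`.
#' @export
generate_cohort <- function(target_rdm, n_subjects = 8, n_runs = 2,
                            n_voxels = 60, noise_sd = 0.5, seed = 1L) {
  D <- validate_rdm(target_rdm)
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(abs(e$values))
  abort_if(min(e$values) < -1e-8 * max(abs(e$values)),
           "target_rdm is not Euclidean-embeddable; most negative eigenvalue of ",
           "the double-centered -D/2 matrix: ", format(min(e$values)))
  keep <- e$values > tol
  k <- sum(keep)
  abort_if(n_voxels < 2 * k,
           "n_voxels must be at least twice the embedding rank (need >= ",
           2 * k, ", got ", n_voxels, ")")
  U <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  m <- floor(n_voxels / 2)

  out <- withr::with_seed(seed, {
    # Frame Z (k x m) with Z Z^T = diag(lam) and equal column norms.
    W <- t(qr.Q(qr(matrix(rnorm(m * k), m, k))))  # orthonormal rows
    Z <- balance_frame(sqrt(lam) * W)
    Y <- cbind(Z, -Z) / sqrt(2)
    if (2 * m < n_voxels) Y <- cbind(Y, rep(0, k))  # odd voxel count: one silent voxel
    Y <- Y[, sample(n_voxels), drop = FALSE]       # shuffle voxel order
    base <- U %*% Y
    rownames(base) <- rownames(D)
    colnames(base) <- paste0("v", seq_len(n_voxels))
    patterns <- lapply(seq_len(n_subjects), function(s) {
      lapply(seq_len(n_runs), function(r) {
        base + if (noise_sd > 0) matrix(rnorm(n * n_voxels, 0, noise_sd), n) else 0
      })
    })
    list(base = base, patterns = patterns)
  })

  structure(list(patterns = out$patterns, base = out$base,
                 target_rdm = target_rdm, noise_sd = noise_sd,
                 n_subjects = n_subjects, n_runs = n_runs,
                 n_voxels = n_voxels, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# Givens balancing: rotate column pairs of Z (right-multiplication by
# orthogonal matrices, which preserves Z Z^T) until all column norms equal
# sum(lam) / m. Classic constant-diagonal construction; each step fixes one
# column exactly, so convergence takes at most a few sweeps.
balance_frame <- function(Z, tol = 1e-12, max_iter = 10000L) {
  m <- ncol(Z)
  target <- sum(Z^2) / m
  for (it in seq_len(max_iter)) {
    cn <- colSums(Z^2)
    i <- which.max(cn); j <- which.min(cn)
    if (cn[i] - target < tol && target - cn[j] < tol) break
    zi <- Z[, i]; zj <- Z[, j]
    a <- sum(zi^2); b <- sum(zj^2); cc <- sum(zi * zj)
    f <- function(t) a * cos(t)^2 + b * sin(t)^2 + 2 * cc * sin(t) * cos(t) - target
    t0 <- stats::uniroot(f, c(0, pi / 2), tol = 1e-14)$root
    Z[, i] <- cos(t0) * zi + sin(t0) * zj
    Z[, j] <- -sin(t0) * zi + cos(t0) * zj
  }
  Z
}

#' Write a cohort to per-run CSV files plus a JSON manifest
#'
#' Each run's condition x voxel matrix is written as a labelled CSV; the
#' manifest records the file layout, seed and generator parameters needed
#' to reproduce the cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (s in seq_len(cohort$n_subjects)) {
    for (r in seq_len(cohort$n_runs)) {
      f <- sprintf("sub%02d_run%02d.csv", s, r)
      write.csv(as.data.frame(cohort$patterns[[s]][[r]]),
                file.path(dir, f), row.names = TRUE)
      paths[[length(paths) + 1]] <- list(subject = s, run = r, file = f)
    }
  }
  manifest <- list(
    n_subjects = cohort$n_subjects, n_runs = cohort$n_runs,
    n_voxels = cohort$n_voxels, noise_sd = cohort$noise_sd,
    seed = cohort$seed, conditions = rownames(cohort$base),
    runs = paths
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Average a cohort subject's patterns across runs
#'
#' @param cohort a `synthetic_cohort`.
#' @param subject subject index.
#' @return Condition x voxel matrix, the mean over runs.
#' @export
average_runs <- function(cohort, subject) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  Reduce(`+`, cohort$patterns[[subject]]) / cohort$n_runs
}

#' Generate labelled unit-activation sets with a planted informative subset
#'
#' Emulates recording a high-dimensional network layer over a stimulus set
#' labelled "low"/"high" on one or more binary scene properties. For the
#' focal (first) property, a small subset of informative units responds with
#' class means at `-effect_size / 2` and `+effect_size / 2` (unit noise SD);
#' each informative unit carries its own seeded response polarity (some
#' prefer "high", some "low", as units of a real network would), so the
#' planted signal is not a common-mode offset and survives pattern
#' normalization across units. Every other unit, and every unit for the
#' remaining properties, is pure standard Gaussian noise. Labels are
#' balanced. Defaults emulate a convolutional layer in which
#' affordance-informative units are sparse.
#'
#' @param n_images images per property (must be even; half per class).
#' @param n_units total units.
#' @param n_informative size of the informative subset (<= `n_units`).
#' @param effect_size mean class separation, in units of the noise SD.
#' @param n_properties number of binary scene properties (>= 1); only the
#'   first carries the planted signal.
#' @param seed integer seed.
#' @return A `labeled_activations`: list with `activations` (image x unit
#'   matrix), `labels` (data frame, one factor column per property),
#'   `informative_units` (integer indices) and `effect_size`.
#' @export
generate_labeled_activations <- function(n_images = 100, n_units = 2000,
                                         n_informative = 50, effect_size = 2,
                                         n_properties = 1, seed = 1L) {
  abort_if(n_images %% 2 != 0,
           "n_images must be even so the low/high classes are balanced")
  abort_if(n_informative > n_units, "n_informative must be <= n_units")
  withr::with_seed(seed, {
    act <- matrix(rnorm(n_images * n_units), n_images, n_units)
    labels <- as.data.frame(lapply(seq_len(n_properties), function(p) {
      factor(sample(rep(c("low", "high"), n_images / 2)),
             levels = c("low", "high"))
    }))
    names(labels) <- paste0("property", seq_len(n_properties))
    informative <- sort(sample(n_units, n_informative))
    polarity <- sample(c(-1, 1), n_informative, replace = TRUE)
    signs <- ifelse(labels[[1]] == "high", 1, -1)
    act[, informative] <- act[, informative] +
      outer(signs, polarity) * effect_size / 2
    rownames(act) <- paste0("img", seq_len(n_images))
    colnames(act) <- paste0("u", seq_len(n_units))
    structure(list(activations = act, labels = labels,
                   informative_units = informative, polarity = polarity,
                   effect_size = effect_size, seed = as.integer(seed)),
              class = "labeled_activations")
  })
}
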