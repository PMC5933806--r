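#' Spearman RSA between two RDMs
#'
#' Spearman rank correlation of the two off-diagonal upper-triangle vectors
#' (average ranks on ties). A constant vector makes the correlation
#' undefined; `NA` is returned with a warning.
#'
#' @param rdm_a,rdm_b [rdm()]s sharing labels (>= 4 conditions).
#' @return The correlation `rho` (double).
#' @export
spearman_rsa <- function(rdm_a, rdm_b) {
  check_rdm_pair(rdm_a, rdm_b)
  va <- rdm_vec(rdm_a); vb <- rdm_vec(rdm_b)
  if (sd(va) < 1e-15 || sd(vb) < 1e-15) {
    warning("constant dissimilarity vector; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(va, vb, method = "spearman")
}

check_rdm_pair <- function(a, b, min_n = 4) {
  abort_if(nrow(as.matrix(a)) < min_n, "need at least ", min_n, " conditions")
  abort_if(!identical(rdm_labels(a), rdm_labels(b)),
           "RDMs must share labels and label order")
}

#' Bootstrap standard error by condition subsampling
#'
#' Resamples the stimulus labels of the RDMs: on each iteration the same
#' random condition subset of size `round(fraction * n)` (drawn without
#' replacement, so the unused diagonal never enters) is applied jointly to
#' both RDMs and the statistic is recomputed. The SE is the standard
#' deviation of the resampled statistics.
#'
#' @param rdm_a,rdm_b [rdm()]s sharing labels.
#' @param statistic_fn function of two RDMs returning a scalar
#'   (default [spearman_rsa()]).
#' @param n_iterations bootstrap iterations.
#' @param fraction subsample fraction (subset size must stay >= 4).
#' @param seed integer seed.
#' @return List with `se`, `values` (per-iteration statistics), and settings.
#' @export
bootstrap_se <- function(rdm_a, rdm_b, statistic_fn = spearman_rsa,
                         n_iterations = 5000, fraction = 0.9, seed = 0L) {
  check_rdm_pair(rdm_a, rdm_b)
  n <- nrow(as.matrix(rdm_a))
  m <- round(fraction * n)
  abort_if(m < 4, "subset size ", m, " is too small (need >= 4)")
  A <- as.matrix(rdm_a); B <- as.matrix(rdm_b)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      idx <- sample(n, m)
      statistic_fn(rdm_subset(A, idx), rdm_subset(B, idx))
    }, numeric(1))
  })
  list(se = sd(vals), values = vals, n_iterations = n_iterations,
       fraction = fraction, seed = as.integer(seed))
}

#' Permutation test for an RDM correlation
#'
#' The rows and columns of one RDM are jointly permuted by a single random
#' condition permutation per iteration and the statistic recomputed. The
#' one-tailed p-value is `(sum(R_perm >= R_test) + 1) / (N + 1)`; its floor
#' is `1 / (N + 1)`.
#'
#' @param rdm_a,rdm_b [rdm()]s sharing labels (>= 4 conditions).
#' @param n_iterations number of permutations `N`.
#' @param seed integer seed.
#' @return List with `p_value`, `statistic` (observed rho), `perm_values`,
#'   `n_iterations`, `seed`.
#' @export
permutation_test <- function(rdm_a, rdm_b, n_iterations = 5000, seed = 0L) {
  check_rdm_pair(rdm_a, rdm_b)
  A <- as.matrix(rdm_a); B <- as.matrix(rdm_b)
  n <- nrow(A)
  ra <- rank(A[upper.tri(A)])
  r_test <- cor(ra, rank(B[upper.tri(B)]))
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      p <- sample(n)
      Bp <- B[p, p]
      cor(ra, rank(Bp[upper.tri(Bp)]))
    }, numeric(1))
  })
  p <- (sum(perm >= r_test) + 1) / (n_iterations + 1)
  list(p_value = p, statistic = r_test, perm_values = perm,
       n_iterations = n_iterations, seed = as.integer(seed))
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values.
#' @param m number of comparisons (>= `length(p_values)`).
#' @return `pmin(1, p_values * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  abort_if(m < length(p_values), "m must be >= the number of p-values")
  pmin(1, p_values * m)
}

#' Noise ceiling from subject-level RDMs
#'
#' The mean Spearman correlation of each subject-level RDM to the group
#' RDM (the mean over all subjects, subject included). The ceiling is the
#' RDM correlation an ideal model -- one that matches the average subject --
#' would attain given inter-subject variability.
#'
#' @param subject_rdms list of >= 2 [rdm()]s sharing labels.
#' @return A `noise_ceiling`: list with `value` and `per_subject`.
#' @export
noise_ceiling <- function(subject_rdms) {
  abort_if(length(subject_rdms) < 2, "need at least two subjects")
  g <- group_rdm(subject_rdms)
  per <- vapply(subject_rdms, spearman_rsa, numeric(1), rdm_b = g)
  structure(list(value = mean(per), per_subject = per),
            class = "noise_ceiling")
}

# R^2 of an OLS fit of y on X plus intercept (fast path used everywhere).
r2_ols <- function(y, X) {
  qx <- qr(cbind(1, X))
  res <- qr.resid(qx, y)
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-300) return(NA_real_)
  1 - sum(res^2) / tss
}

#' Multiple-regression RSA
#'
#' Ordinary-least-squares fit of the target RDM's dissimilarity vector on
#' the predictor RDMs' vectors plus an intercept.
#'
#' @param target an [rdm()].
#' @param predictors a single [rdm()] or (optionally named) list of them,
#'   sharing labels with `target`.
#' @return A `regression_rsa`: list with `r_squared`, `coefficients`
#'   (intercept first), `n_pairs`.
#' @export
regression_rsa <- function(target, predictors) {
  if (!is.list(predictors)) predictors <- list(predictors)
  abort_if(length(predictors) < 1, "need at least one predictor")
  for (p in predictors) check_rdm_pair(target, p)
  y <- rdm_vec(target)
  X <- vapply(predictors, rdm_vec, numeric(length(y)))
  X <- matrix(X, nrow = length(y))
  colnames(X) <- names(predictors) %||% paste0("x", seq_len(ncol(X)))
  XX <- cbind(`(Intercept)` = 1, X)
  qx <- qr(XX)
  if (qx$rank < ncol(XX)) {
    dep <- setdiff(colnames(XX), colnames(XX)[qx$pivot[seq_len(qx$rank)]])
    stop("perfectly collinear predictors: ", paste(dep, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(r_squared = r2, coefficients = beta, n_pairs = length(y)),
            class = "regression_rsa")
}

#' Commonality analysis of a two-predictor RDM regression
#'
#' Partitions the explained variance `R2_12` of the two-predictor OLS model
#' into unique and common components:
#' `gamma1 = R2_12 - R2_2` (unique to X1), `gamma2 = R2_12 - R2_1`,
#' `gamma12 = R2_1 + R2_2 - R2_12` (common), and reports the shared-variance
#' percentage `SV = 100 * gamma12 / (gamma12 + gamma1)` -- the percentage of
#' X1's explained variance that is common with X2. When X1 explains nothing
#' (`R2_1 = 0`) SV is undefined and flagged.
#'
#' @param target,x1,x2 [rdm()]s sharing labels.
#' @return A `commonality_result`: list with `r2_full`, `r2_x1`, `r2_x2`,
#'   `gamma1`, `gamma2`, `gamma12`, `shared_variance_pct`, `sv_defined`.
#' @export
commonality <- function(target, x1, x2) {
  check_rdm_pair(target, x1); check_rdm_pair(target, x2)
  y <- rdm_vec(target)
  v1 <- rdm_vec(x1); v2 <- rdm_vec(x2)
  r2_1 <- r2_ols(y, v1)
  r2_2 <- r2_ols(y, v2)
  r2_12 <- r2_ols(y, cbind(v1, v2))
  gamma1 <- r2_12 - r2_2
  gamma2 <- r2_12 - r2_1
  gamma12 <- r2_1 + r2_2 - r2_12
  denom <- gamma12 + gamma1            # algebraically equals r2_1
  sv_defined <- is.finite(denom) && denom > 1e-12
  sv <- if (sv_defined) 100 * gamma12 / denom else NA_real_
  structure(list(r2_full = r2_12, r2_x1 = r2_1, r2_x2 = r2_2,
                 gamma1 = gamma1, gamma2 = gamma2, gamma12 = gamma12,
                 shared_variance_pct = sv, sv_defined = sv_defined),
            class = "commonality_result")
}

#' Bootstrap contrast of two shared-variance values
#'
#' Compares `SV(target; x1, x2_a)` against `SV(target; x1, x2_b)` by joint
#' condition subsampling of all four RDMs (without replacement, same subset
#' everywhere). Reports the 5th percentile of the SV difference
#' distribution -- the lower bound of a one-tailed 95% test -- and whether it
#' exceeds zero.
#'
#' @param target,x1,x2_a,x2_b [rdm()]s sharing labels.
#' @param n_iterations,fraction,seed as in [bootstrap_se()].
#' @return List with `lower_percentile` (5th percentile of `SV_a - SV_b`),
#'   `exceeds_zero`, `differences`, and settings.
#' @export
bootstrap_sv_contrast <- function(target, x1, x2_a, x2_b,
                                  n_iterations = 5000, fraction = 0.9,
                                  seed = 0L) {
  for (p in list(x1, x2_a, x2_b)) check_rdm_pair(target, p)
  n <- nrow(as.matrix(target))
  m <- round(fraction * n)
  abort_if(m < 4, "subset size ", m, " is too small (need >= 4)")
  Ts <- as.matrix(target); X1 <- as.matrix(x1)
  A <- as.matrix(x2_a); B <- as.matrix(x2_b)
  diffs <- withr::with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      idx <- sample(n, m)
      sa <- commonality(rdm_subset(Ts, idx), rdm_subset(X1, idx),
                        rdm_subset(A, idx))$shared_variance_pct
      sb <- commonality(rdm_subset(Ts, idx), rdm_subset(X1, idx),
                        rdm_subset(B, idx))$shared_variance_pct
      sa - sb
    }, numeric(1))
  })
  q5 <- unname(quantile(diffs, 0.05, na.rm = TRUE))
  list(lower_percentile = q5, exceeds_zero = isTRUE(q5 > 0),
       differences = diffs, n_iterations = n_iterations,
       fraction = fraction, seed = as.integer(seed))
}

#' One-stop RSA comparison of two RDMs
#'
#' Bundles [spearman_rsa()], [bootstrap_se()], [permutation_test()] and
#' [bonferroni()] into a single result record.
#'
#' @param rdm_a,rdm_b [rdm()]s sharing labels.
#' @param n_iterations iterations for both bootstrap and permutation.
#' @param fraction bootstrap subsample fraction.
#' @param m_comparisons Bonferroni comparison count.
#' @param seed integer seed.
#' @return An `rsa_result`: list with `statistic`, `bootstrap_se`,
#'   `p_value`, `p_corrected`, `n_iterations`, `resample_fraction`, `seed`.
#' @export
rsa_compare <- function(rdm_a, rdm_b, n_iterations = 5000, fraction = 0.9,
                        m_comparisons = 1, seed = 0L) {
  rho <- spearman_rsa(rdm_a, rdm_b)
  bs <- bootstrap_se(rdm_a, rdm_b, n_iterations = n_iterations,
                     fraction = fraction, seed = seed)
  pt <- permutation_test(rdm_a, rdm_b, n_iterations = n_iterations,
                         seed = derive_seed(seed, 1))
  structure(list(statistic = rho, bootstrap_se = bs$se,
                 p_value = pt$p_value,
                 p_corrected = unname(bonferroni(pt$p_value, m_comparisons)),
                 n_iterations = n_iterations, resample_fraction = fraction,
                 seed = as.integer(seed)),
            class = "rsa_result")
}
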