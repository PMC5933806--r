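# Spearman RSA, bootstrap, permutation, noise ceiling, regression RSA,
# commonality and the SV contrast.

test_that("spearman RSA behaves as a rank statistic", {
  a <- random_euclidean_rdm(6, seed = 1)
  expect_equal(spearman_rsa(a, a), 1)
  b <- rdm(exp(as.matrix(a)) - diag(exp(0), 6), labels = rdm_labels(a))
  expect_equal(spearman_rsa(a, b), 1)

  # 4-condition worked example against a hand-rank oracle over the six
  # unordered pairs (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  A <- rdm(matrix(c(0, 1, 2, 3, 1, 0, 4, 5, 2, 4, 0, 6, 3, 5, 6, 0), 4))
  B <- rdm(matrix(c(0, 2, 1, 5, 2, 0, 3, 4, 1, 3, 0, 7, 5, 4, 7, 0), 4))
  va <- rank(c(1, 2, 4, 3, 5, 6))
  vb <- rank(c(2, 1, 3, 5, 4, 7))
  oracle <- cor(va, vb)
  expect_equal(spearman_rsa(A, B), oracle, tolerance = 1e-12)
  expect_warning(spearman_rsa(a, rdm(matrix(1, 6, 6) - diag(1, 6),
                                     labels = rdm_labels(a))),
                 "constant")
})

test_that("bootstrap subsampling yields zero SE in degenerate cases", {
  a <- random_euclidean_rdm(10, seed = 2)
  expect_equal(bootstrap_se(a, a, n_iterations = 50, seed = 1)$se, 0)
  b <- random_euclidean_rdm(10, seed = 3)
  expect_equal(bootstrap_se(a, b, n_iterations = 50, fraction = 1,
                            seed = 1)$se, 0)
  expect_error(bootstrap_se(rdm_subset(a, 1:4), rdm_subset(b, 1:4),
                            fraction = 0.5), "too small")
})

test_that("bootstrap SE shrinks with condition count for planted signal", {
  se_for <- function(n) {
    withr::with_seed(n, {
      base <- matrix(rnorm(n * 20), n)
      a <- compute_rdm(base)
      b <- compute_rdm(base + matrix(rnorm(n * 20, 0, 0.7), n))
    })
    bootstrap_se(a, b, n_iterations = 300, seed = 5)$se
  }
  expect_lt(se_for(50), se_for(10))
})

test_that("permutation p-values follow the +1 formula and are seeded", {
  withr::with_seed(4, {
    base <- matrix(rnorm(12 * 20), 12)
    a <- compute_rdm(base)
    b <- compute_rdm(base + matrix(rnorm(12 * 20, 0, 0.1), 12))
  })
  pt <- permutation_test(a, b, n_iterations = 200, seed = 11)
  expect_equal(pt$p_value, 1 / 201)  # observed exceeds every permutation
  pt2 <- permutation_test(a, b, n_iterations = 200, seed = 11)
  expect_identical(pt$p_value, pt2$p_value)
  expect_error(permutation_test(rdm_subset(a, 1:3), rdm_subset(b, 1:3)),
               "at least 4")
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(c(0.2, 0.3)), c(0.4, 0.6))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), ">=")
})

test_that("noise ceiling matches a hand computation and tracks noise", {
  a <- random_euclidean_rdm(4, seed = 5)
  expect_equal(noise_ceiling(list(a, a))$value, 1)
  b <- random_euclidean_rdm(4, seed = 6)
  g <- group_rdm(list(a, b))
  oracle <- mean(c(spearman_rsa(a, g), spearman_rsa(b, g)))
  nc <- noise_ceiling(list(a, b))
  expect_equal(nc$value, oracle)
  expect_equal(nc$value, mean(nc$per_subject))
  expect_error(noise_ceiling(list(a)), "two subjects")

  D <- random_zscored_rdm(12, 40, seed = 7)
  ceil <- vapply(c(0.2, 2), function(ns) {
    co <- generate_cohort(D, n_subjects = 4, n_runs = 2, n_voxels = 30,
                          noise_sd = ns, seed = 8)
    noise_ceiling(lapply(1:4, function(s) compute_rdm(average_runs(co, s))))$value
  }, numeric(1))
  expect_gt(ceil[1], ceil[2])
})

test_that("regression RSA reduces to known OLS identities", {
  y <- random_euclidean_rdm(8, seed = 9)
  x <- random_euclidean_rdm(8, seed = 10)
  fit <- regression_rsa(y, x)
  expect_equal(fit$r_squared, cor(rdm_vec(y), rdm_vec(x))^2,
               tolerance = 1e-12)

  y2 <- rdm(2 * as.matrix(x) + 3 - diag(3, 8), labels = rdm_labels(x))
  fit2 <- regression_rsa(y2, x)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit2$coefficients), c(3, 2), tolerance = 1e-10)

  # orthogonalized predictors decompose R^2 additively
  v1 <- rdm_vec(x)
  z <- rdm_vec(random_euclidean_rdm(8, seed = 11))
  v2 <- stats::resid(stats::lm(z ~ v1)) + mean(z)
  v2 <- v2 - min(v2)
  m2 <- matrix(0, 8, 8); m2[upper.tri(m2)] <- v2; m2 <- m2 + t(m2)
  x2 <- rdm(m2, labels = rdm_labels(x))
  r2_sum <- regression_rsa(y, x)$r_squared +
    regression_rsa(y, x2)$r_squared
  r2_joint <- regression_rsa(y, list(a = x, b = x2))$r_squared
  expect_equal(r2_joint, r2_sum, tolerance = 1e-10)

  dup <- rdm(2 * as.matrix(x), labels = rdm_labels(x))
  expect_error(regression_rsa(y, list(a = x, b = dup)), "collinear.*b")
})

test_that("commonality evaluates the variance-partitioning formulas", {
  # planted R^2s: construct y = a*v1' + b*v2' with controlled overlap, then
  # verify against direct evaluation of the formulas
  y <- random_euclidean_rdm(10, seed = 12)
  x1 <- random_euclidean_rdm(10, seed = 13)
  x2 <- random_euclidean_rdm(10, seed = 14)
  cm <- commonality(y, x1, x2)
  r2 <- function(p) regression_rsa(y, p)$r_squared
  expect_equal(cm$gamma1, cm$r2_full - r2(x2), tolerance = 1e-12)
  expect_equal(cm$gamma12, r2(x1) + r2(x2) - cm$r2_full, tolerance = 1e-12)
  expect_equal(cm$shared_variance_pct,
               100 * cm$gamma12 / (cm$gamma12 + cm$gamma1), tolerance = 1e-12)

  # duplicate predictor: everything X1 explains is shared
  x2dup <- rdm(0.5 * as.matrix(x1), labels = rdm_labels(x1))
  expect_equal(commonality(y, x1, x2dup)$shared_variance_pct, 100,
               tolerance = 1e-6)

  # orthogonalized second predictor shares ~nothing
  v1 <- rdm_vec(x1); vy <- rdm_vec(y)
  z <- rdm_vec(random_euclidean_rdm(10, seed = 15))
  vres <- stats::resid(stats::lm(z ~ v1 + vy))
  m <- matrix(0, 10, 10); m[upper.tri(m)] <- vres - min(vres); m <- m + t(m)
  cm0 <- commonality(y, x1, rdm(m, labels = rdm_labels(x1)))
  expect_lt(abs(cm0$shared_variance_pct), 1)
})

test_that("direct formula example: R2s of 0.6/0.5/0.3 give SV = 40%", {
  # synthesize predictors with exactly R2_1 = 0.5, R2_2 = 0.3, R2_12 = 0.6:
  # with unit-norm predictors u1, u2 at correlation rho and projections
  # a = sqrt(0.5), b = sqrt(0.3), the joint fit explains
  # (a^2 + b^2 - 2ab rho) / (1 - rho^2); solve that quadratic for rho
  a <- sqrt(0.5); b <- sqrt(0.3)
  rho <- (2 * a * b - sqrt((2 * a * b)^2 - 4 * 0.6 * (a^2 + b^2 - 0.6))) /
    (2 * 0.6)
  n <- 200
  withr::with_seed(16, {
    q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, -1]
  })
  e1 <- q[, 1]; e2 <- q[, 2]; e3 <- q[, 3]
  u1 <- e1
  u2 <- rho * e1 + sqrt(1 - rho^2) * e2
  beta <- (b - a * rho) / sqrt(1 - rho^2)
  y <- a * e1 + beta * e2 + sqrt(1 - a^2 - beta^2) * e3
  r2 <- function(X) summary(stats::lm(y ~ X))$r.squared
  expect_equal(r2(u1), 0.5, tolerance = 1e-10)
  expect_equal(r2(u2), 0.3, tolerance = 1e-10)
  expect_equal(r2(cbind(u1, u2)), 0.6, tolerance = 1e-10)
  g1 <- r2(cbind(u1, u2)) - r2(u2)
  g12 <- r2(u1) + r2(u2) - r2(cbind(u1, u2))
  expect_equal(g1, 0.3, tolerance = 1e-8)
  expect_equal(g12, 0.2, tolerance = 1e-8)
  expect_equal(100 * g12 / (g12 + g1), 40, tolerance = 1e-6)
})

test_that("SV bootstrap contrast separates planted from degenerate cases", {
  y <- random_euclidean_rdm(12, seed = 17)
  x1 <- rdm(as.matrix(y) * 0.8, labels = rdm_labels(y))  # strong predictor
  same <- bootstrap_sv_contrast(y, x1, x1, x1, n_iterations = 100, seed = 1)
  expect_equal(same$lower_percentile, 0)
  expect_false(same$exceeds_zero)

  # x2_a duplicates x1 (SV = 100); x2_b is an independent RDM (SV ~ small)
  x2b <- random_euclidean_rdm(12, seed = 18)
  ct <- bootstrap_sv_contrast(y, x1, x1, x2b, n_iterations = 200, seed = 2)
  expect_gt(ct$lower_percentile, 0)
  ct2 <- bootstrap_sv_contrast(y, x1, x1, x2b, n_iterations = 200, seed = 2)
  expect_identical(ct$lower_percentile, ct2$lower_percentile)
})

test_that("rsa_compare bundles the inference record", {
  withr::with_seed(19, {
    base <- matrix(rnorm(12 * 30), 12)
    a <- compute_rdm(base)
    b <- compute_rdm(base + matrix(rnorm(12 * 30, 0, 0.5), 12))
  })
  res <- rsa_compare(a, b, n_iterations = 200, m_comparisons = 4, seed = 3)
  expect_equal(res$p_corrected, min(1, res$p_value * 4))
  expect_gte(res$p_value, 1 / 201)
  td <- tidy(res)
  expect_equal(td$statistic, res$statistic)
})
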