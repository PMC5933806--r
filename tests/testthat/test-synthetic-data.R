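# Scene, path-map, cohort and activation generators.

test_that("scene rendering is deterministic, mirror-symmetric and truthful", {
  sp <- scene_spec(image_size = c(101, 101), opening_azimuths = c(45, 135),
                   opening_widths = 12)
  img1 <- render_scene(sp)
  img2 <- render_scene(sp)
  expect_identical(unclass(img1), unclass(img2))
  expect_equal(attr(img1, "azimuths"), c(45, 135))
  expect_true(all(img1 >= 0 & img1 <= 1))

  # single centered doorway: image is exactly left-right symmetric, and
  # rendering the mirrored spec equals mirroring the rendering
  sp90 <- scene_spec(image_size = c(101, 101), opening_azimuths = 90)
  i90 <- render_scene(sp90)
  expect_equal(unclass(i90), unclass(i90)[, ncol(i90):1],
               ignore_attr = TRUE)
  mir <- render_scene(mirror_spec(sp))
  expect_equal(unclass(mir), unclass(img1)[, ncol(img1):1],
               ignore_attr = TRUE)
})

test_that("overlapping openings are rejected with the conflicting azimuths", {
  sp <- scene_spec(image_size = c(101, 101), opening_azimuths = c(88, 92),
                   opening_widths = 20)
  expect_error(render_scene(sp), "overlap.*8[89]", ignore.case = TRUE)
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(opening_azimuths = numeric(0)), "at least one")
  expect_error(scene_spec(opening_azimuths = 180), "strictly within")
  expect_error(scene_spec(opening_azimuths = 90, opening_widths = -1),
               "positive")
})

test_that("zero-noise rater paths put all mass on the planted rays", {
  hm <- simulate_rater_paths(90, n_raters = 5, angular_noise_sd = 0,
                             image_size = c(101, 101), seed = 1, blur_sd = 0)
  cx <- attr(hm, "origin")[["col"]]
  expect_equal(sum(hm[, cx]), sum(hm))
  expect_equal(sum(hm), 5)  # one unit of mass per rater

  # even rater count, two azimuths: exact 50/50 split between the rays
  hm2 <- simulate_rater_paths(c(60, 120), n_raters = 10, angular_noise_sd = 0,
                              image_size = c(101, 101), seed = 1, blur_sd = 0)
  left <- sum(hm2[, 1:(cx - 1)])
  right <- sum(hm2[, (cx + 1):ncol(hm2)])
  expect_equal(left, right, tolerance = 1e-12)
  expect_equal(left + right + sum(hm2[, cx]), 10)
})

test_that("rater-path mass is conserved under blurring", {
  hm <- simulate_rater_paths(c(70, 110), n_raters = 8, angular_noise_sd = 3,
                             image_size = c(101, 101), seed = 2, blur_sd = 2)
  expect_equal(sum(hm), 8, tolerance = 1e-9)
  expect_true(all(hm >= 0))
  expect_error(simulate_rater_paths(numeric(0), 5), "non-empty")
})

test_that("noisy rater histograms recover planted azimuths", {
  # Monte-Carlo with the generator itself: at 100 raters and 5-degree
  # angular noise the top-2 smoothed-histogram peaks sit within 3 degrees
  # of the planted azimuths in >= 90% of replicates (the peak of a
  # kernel-smoothed angular density over ~50 draws per ray jitters by a
  # couple of degrees; exact localization is the zero-noise case above)
  truth <- c(60, 120)
  hits <- vapply(1:100, function(r) {
    hm <- simulate_rater_paths(truth, n_raters = 100, angular_noise_sd = 5,
                               image_size = c(101, 101), seed = 1000 + r)
    h <- affordance_histogram(hm)
    top2 <- h$bin_deg[order(h$smoothed, decreasing = TRUE)[1:2]]
    all(vapply(top2, function(b) min(abs(b - truth)) <= 3, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("zero-noise cohorts reproduce the target RDM exactly", {
  D <- random_zscored_rdm(12, 40, seed = 5)
  co <- generate_cohort(D, n_subjects = 3, n_runs = 2, n_voxels = 40,
                        noise_sd = 0, seed = 9)
  for (s in 1:3) {
    rec <- compute_rdm(average_runs(co, s))
    expect_lt(max(abs(as.matrix(rec) - as.matrix(D))), 1e-6)
  }
  # subject RDMs identical at zero noise
  expect_equal(as.matrix(compute_rdm(average_runs(co, 1))),
               as.matrix(compute_rdm(average_runs(co, 2))))
  # determinism
  co2 <- generate_cohort(D, n_subjects = 3, n_runs = 2, n_voxels = 40,
                         noise_sd = 0, seed = 9)
  expect_identical(co$patterns, co2$patterns)

  # CSV + manifest export round-trips a run matrix
  d <- withr::local_tempdir()
  write_cohort_csv(co, d)
  mf <- jsonlite::read_json(file.path(d, "cohort_manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$n_subjects, 3)
  expect_equal(nrow(mf$runs), 6)
  back <- as.matrix(read.csv(file.path(d, mf$runs$file[1]), row.names = 1))
  expect_equal(unname(back), unname(co$patterns[[1]][[1]]), tolerance = 1e-12)
})

test_that("cohort generation enforces embeddability and voxel count", {
  # square roots 1, 1, 3 violate the triangle inequality, so no Euclidean
  # configuration exists
  bad <- rdm(matrix(c(0, 1, 9, 1, 0, 1, 9, 1, 0), 3))
  expect_error(generate_cohort(bad, n_voxels = 60), "negative eigenvalue")
  D <- random_zscored_rdm(10, 30, seed = 1)
  expect_error(generate_cohort(D, n_voxels = 4), "twice the embedding rank")
})

test_that("cohort RSA to the target degrades with noise", {
  D <- random_zscored_rdm(15, 50, seed = 11)
  mean_rho <- vapply(c(0, 0.5, 1, 2), function(ns) {
    mean(vapply(1:25, function(r) {
      co <- generate_cohort(D, n_subjects = 3, n_runs = 2, n_voxels = 40,
                            noise_sd = ns, seed = 3000 + r)
      g <- group_rdm(lapply(1:3, function(s) compute_rdm(average_runs(co, s))))
      spearman_rsa(g, D)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean_rho[1], 1, tolerance = 1e-8)
  expect_true(all(diff(mean_rho) < 0))
})

test_that("labelled activations plant the requested class structure", {
  la <- generate_labeled_activations(n_images = 100, n_units = 200,
                                     n_informative = 50, effect_size = 6,
                                     seed = 4)
  expect_equal(as.vector(table(la$labels[[1]])), c(50, 50))
  expect_length(la$informative_units, 50)
  # determinism
  la2 <- generate_labeled_activations(n_images = 100, n_units = 200,
                                      n_informative = 50, effect_size = 6,
                                      seed = 4)
  expect_identical(la$activations, la2$activations)
  # planted separation shows up in the informative units, signed by each
  # unit's response polarity
  inf_means <- colMeans(la$activations[la$labels[[1]] == "high",
                                       la$informative_units]) -
    colMeans(la$activations[la$labels[[1]] == "low", la$informative_units])
  expect_gt(min(inf_means * la$polarity), 3)
  other <- setdiff(seq_len(200), la$informative_units)
  null_means <- colMeans(la$activations[la$labels[[1]] == "high", other]) -
    colMeans(la$activations[la$labels[[1]] == "low", other])
  expect_lt(max(abs(null_means)), 2)
  expect_error(generate_labeled_activations(n_images = 99), "balanced")
})
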