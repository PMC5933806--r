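# Shared fixtures, all generated in code.

# Random z-scored pattern set -> RDM with the canonical identity structure.
random_zscored_rdm <- function(n_cond, n_feat, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_cond * n_feat), n_cond)
    x <- t(scale(t(x)))
    compute_rdm(x, labels = paste0("c", seq_len(n_cond)))
  })
}

# Arbitrary valid (Euclidean) RDM from random point configurations.
random_euclidean_rdm <- function(n_cond, dim = 5, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_cond * dim), n_cond)
    compute_rdm(x, labels = paste0("c", seq_len(n_cond)))
  })
}

# Peaked affordance-like histograms for a set of scenes.
peaked_histograms <- function(azimuths, width = 12, noise = 0.02, seed = 1) {
  withr::with_seed(seed, {
    lapply(azimuths, function(mu) {
      th <- 0:179
      v <- exp(-0.5 * ((th - mu) / width)^2) + abs(rnorm(180, 0, noise))
      affordance_histogram(v)
    })
  })
}

# An adapter whose single "unit" is the mean intensity over a fixed region;
# used for planted receptive-field recovery.
region_mean_adapter <- function(rows, cols) {
  activation_adapter(function(images) {
    vals <- vapply(images, function(img) mean(img[rows, cols]), numeric(1))
    list(probe = matrix(vals, ncol = 1))
  })
}

# Scenes whose affordance-relevant structure (junction + path wedges) lies
# strictly in the lower image half; the upper half varies only in
# affordance-irrelevant texture frequency and wall luminance.
planted_lower_half_scenes <- function(seed, n = 16) {
  withr::with_seed(seed, {
    az <- runif(n, 50, 130)
    tf <- runif(n, 0.03, 0.09)
    wl <- runif(n, 0.42, 0.5)
  })
  imgs <- lapply(seq_len(n), function(i) {
    render_scene(scene_spec(image_size = c(101, 101),
                            opening_azimuths = az[i], horizon_frac = 0.6,
                            wall_luminance = wl[i], door_luminance = wl[i],
                            path_contrast = 0.4, texture_frequency = tf[i]))
  })
  names(imgs) <- paste0("s", seq_len(n))
  hists <- lapply(seq_len(n), function(i) {
    affordance_histogram(simulate_rater_paths(
      az[i], n_raters = 40, angular_noise_sd = 2,
      image_size = c(101, 101), seed = seed * 100 + i))
  })
  names(hists) <- names(imgs)
  list(images = imgs, azimuths = az,
       target = compute_rdm(affordance_patterns(hists)))
}

tiny_network <- function(seed = 7) {
  build_network(network_config(
    input_size = c(32, 32), channels = 1,
    layers = list(conv_spec(4, 5, stride = 2), relu_spec(), max_pool_spec(2, 2),
                  local_norm_spec(),
                  conv_spec(8, 3), relu_spec(),
                  dense_spec(16)),
    seed = seed
  ))
}
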