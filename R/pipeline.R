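#' Configuration for the end-to-end synthetic study
#'
#' All stage parameters are validated up front; every stochastic stage
#' derives its own seed deterministically from `seed`.
#'
#' @param seed master seed.
#' @param out_dir output directory (`NULL` disables artifact writing).
#' @param n_scenes number of synthetic scenes (conditions).
#' @param scene_size rendered scene size in pixels.
#' @param n_raters,rater_noise_sd rater-path simulation parameters.
#' @param n_subjects,n_runs,n_voxels,noise_sd cohort parameters.
#' @param network a [network_config()].
#' @param pca_k principal components per layer (capped at available rank).
#' @param n_iterations bootstrap/permutation/resampling iterations for the
#'   end-to-end run (the per-operation default of 5000 is deliberately
#'   larger; the pipeline favors desk-scale turnaround).
#' @param slice_height,slice_stride slice-occlusion geometry, pixels.
#' @param rf_image_size scene size used for receptive-field mapping.
#' @param rf_n_units number of units selected for receptive-field analyses.
#' @param rf_patch_size,rf_stride occluder geometry for discrepancy mapping.
#' @param cluster_patch patch side for unit-response clustering.
#' @param cls_n_images,cls_n_units,cls_n_informative,cls_effect_size
#'   labelled-activation generator parameters for the classification stage.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            n_scenes = 20, scene_size = c(227, 227),
                            n_raters = 20, rater_noise_sd = 5,
                            n_subjects = 8, n_runs = 2, n_voxels = 60,
                            noise_sd = 0.5,
                            network = network_config(),
                            pca_k = 45, n_iterations = 500,
                            slice_height = 41, slice_stride = 5,
                            rf_image_size = c(64, 64), rf_n_units = 8,
                            rf_patch_size = 11, rf_stride = 3,
                            cluster_patch = 27,
                            cls_n_images = 100, cls_n_units = 2000,
                            cls_n_informative = 50, cls_effect_size = 2) {
  abort_if(n_scenes < 8, "need at least 8 scenes")
  abort_if(n_subjects < 2, "need at least 2 subjects")
  abort_if(n_runs < 1 || n_iterations < 1, "counts must be positive")
  abort_if(!inherits(network, "network_config"), "network must be a network_config")
  abort_if(slice_height > scene_size[1], "slice taller than the scene")
  abort_if(rf_patch_size > rf_image_size[1], "occluder larger than RF image")
  abort_if(cls_n_informative > cls_n_units, "informative units exceed units")
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end synthetic study
#'
#' Executes the full pipeline in dependency order: scene generation, rater
#' path maps and affordance histograms, the affordance RDM, a synthetic
#' voxel cohort planted with that RDM (subject RDMs computed from
#' run-averaged patterns -- the generator produces calibrated patterns with
#' no per-voxel gain structure, so the gain-normalization chain for raw
#' fMRI patterns is not applied), network layer RDMs, RSA with bootstrap and
#' permutation inference, commonality analysis, the filter and slice
#' experiments, receptive-field mapping with unit clustering, and
#' navigability classification with a unit-resampling null. Artifacts and a
#' reproducibility manifest are written under `config$out_dir` when set.
#' Reruns with the same configuration are identical.
#'
#' @param config a [pipeline_config()].
#' @return A `navrsa_pipeline` result bundle; see [glance.navrsa_pipeline()]
#'   for the one-row summary.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config)
  seed <- config$seed
  write_out <- !is.null(config$out_dir)
  if (write_out) dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- scenes ------------------------------------------------------------
  out$scenes <- pipeline_stage("scenes", {
    specs <- withr::with_seed(derive_seed(seed, 1), {
      lapply(seq_len(config$n_scenes), function(i) {
        n_open <- 1 + (i %% 2)
        az <- sort(runif(n_open, 45, 135))
        while (n_open == 2 && diff(az) < 35) az <- sort(runif(2, 45, 135))
        scene_spec(image_size = config$scene_size, opening_azimuths = az,
                   opening_widths = 14, seed = derive_seed(seed, 100 + i))
      })
    })
    imgs <- lapply(specs, render_scene)
    names(imgs) <- sprintf("scene%02d", seq_along(imgs))
    if (write_out) {
      dir.create(file.path(config$out_dir, "scenes"), showWarnings = FALSE)
      for (nm in names(imgs)) {
        write_image_png(imgs[[nm]],
                        file.path(config$out_dir, "scenes", paste0(nm, ".png")))
      }
    }
    list(specs = specs, images = imgs)
  })
  labels <- names(out$scenes$images)

  # -- affordance histograms and RDM --------------------------------------
  out$affordance <- pipeline_stage("affordance", {
    maps <- lapply(seq_along(out$scenes$specs), function(i) {
      simulate_rater_paths(out$scenes$specs[[i]]$opening_azimuths,
                           n_raters = config$n_raters,
                           angular_noise_sd = config$rater_noise_sd,
                           image_size = config$scene_size,
                           seed = derive_seed(seed, 200 + i))
    })
    hists <- lapply(maps, affordance_histogram)
    names(hists) <- labels
    patterns <- affordance_patterns(hists)
    rdm_aff <- compute_rdm(patterns, labels = labels, source = "affordance")
    if (write_out) {
      dir.create(file.path(config$out_dir, "histograms"), showWarnings = FALSE)
      dir.create(file.path(config$out_dir, "heatmaps"), showWarnings = FALSE)
      for (i in seq_along(labels)) {
        nm <- labels[i]
        write.csv(hists[[nm]],
                  file.path(config$out_dir, "histograms", paste0(nm, ".csv")),
                  row.names = FALSE)
        write.csv(as.data.frame(unclass(maps[[i]])),
                  file.path(config$out_dir, "heatmaps", paste0(nm, ".csv")),
                  row.names = FALSE)
      }
      write_rdm_csv(rdm_aff, file.path(config$out_dir, "rdm_affordance.csv"))
    }
    list(heat_maps = maps, histograms = hists, rdm = rdm_aff)
  })

  # -- synthetic cohort and neural RDMs ------------------------------------
  out$cohort <- pipeline_stage("cohort", {
    cohort <- generate_cohort(out$affordance$rdm,
                              n_subjects = config$n_subjects,
                              n_runs = config$n_runs,
                              n_voxels = config$n_voxels,
                              noise_sd = config$noise_sd,
                              seed = derive_seed(seed, 3))
    subject_rdms <- lapply(seq_len(config$n_subjects), function(s) {
      compute_rdm(average_runs(cohort, s), labels = labels,
                  source = paste0("subject", s))
    })
    grdm <- group_rdm(subject_rdms)
    nc <- noise_ceiling(subject_rdms)
    if (write_out) {
      write_rdm_csv(grdm, file.path(config$out_dir, "rdm_group.csv"))
      write_cohort_csv(cohort, file.path(config$out_dir, "cohort"))
    }
    list(cohort = cohort, subject_rdms = subject_rdms, group_rdm = grdm,
         noise_ceiling = nc)
  })

  # -- network layer RDMs --------------------------------------------------
  out$network <- pipeline_stage("network", {
    net <- build_network(config$network)
    rdms <- layer_rdms(net, out$scenes$images, labels, config$pca_k)
    list(net = net, layer_rdms = rdms)
  })

  # -- RSA inference -------------------------------------------------------
  out$rsa <- pipeline_stage("rsa", {
    neural_vs_aff <- rsa_compare(out$cohort$group_rdm, out$affordance$rdm,
                                 n_iterations = config$n_iterations,
                                 seed = derive_seed(seed, 4))
    lay <- out$network$layer_rdms
    lay <- lay[!vapply(lay, is.null, logical(1))]
    layer_tbl <- purrr::map_dfr(names(lay), function(ly) {
      tibble::tibble(
        layer = ly,
        rho_affordance = spearman_rsa(lay[[ly]], out$affordance$rdm),
        rho_neural = spearman_rsa(lay[[ly]], out$cohort$group_rdm)
      )
    })
    layer_tbl$p_affordance <- vapply(names(lay), function(ly) {
      permutation_test(lay[[ly]], out$affordance$rdm,
                       n_iterations = config$n_iterations,
                       seed = derive_seed(seed, 5))$p_value
    }, numeric(1))
    layer_tbl$p_affordance_corrected <- bonferroni(layer_tbl$p_affordance,
                                                   m = nrow(layer_tbl))
    list(group_vs_affordance = neural_vs_aff, layers = layer_tbl)
  })

  # -- commonality ---------------------------------------------------------
  out$commonality <- pipeline_stage("commonality", {
    lay <- out$network$layer_rdms
    lay <- lay[!vapply(lay, is.null, logical(1))]
    best <- out$rsa$layers$layer[which.max(out$rsa$layers$rho_neural)]
    cm <- commonality(out$cohort$group_rdm, lay[[best]], out$affordance$rdm)
    list(best_layer = best, result = cm)
  })

  # -- stimulus experiments ------------------------------------------------
  targets <- list(affordance = out$affordance$rdm,
                  neural = out$cohort$group_rdm)
  out$features <- pipeline_stage("features", {
    run_feature_experiment(out$scenes$images, out$network$net, targets,
                           pca_k = config$pca_k)
  })
  out$slices <- pipeline_stage("slices", {
    run_slice_experiment(out$scenes$images, out$network$net, targets,
                         slice_height = config$slice_height,
                         stride = config$slice_stride,
                         pca_k = config$pca_k)
  })

  # -- receptive fields ----------------------------------------------------
  out$rf <- pipeline_stage("receptive_fields", {
    small <- lapply(out$scenes$images, resize_bilinear,
                    height = config$rf_image_size[1],
                    width = config$rf_image_size[2])
    acts <- get_activations(out$network$net, small)
    conv_blocks <- grep("^conv", names(acts), value = TRUE)
    block <- conv_blocks[length(conv_blocks)]
    sel <- select_units(acts[[block]], out$affordance$rdm,
                        out$cohort$group_rdm, n = config$rf_n_units)
    units <- sel$unit[sel$selected]
    maps <- lapply(seq_along(small), function(i) {
      map_discrepancy(out$network$net, small[[i]], block, units = units,
                      patch_size = config$rf_patch_size,
                      stride = config$rf_stride,
                      seed = derive_seed(seed, 600 + i))
    })
    resp <- rf_unit_responses(out$network$net, maps, small, units, block,
                              patch = config$cluster_patch)
    emb <- embed_and_cluster_units(resp, k_range = 2:min(10, length(units) - 1),
                                   seed = derive_seed(seed, 7))
    seg <- segment_receptive_field(pixel_map(maps[[resp$top_images$image[1]]],
                                             units[1]),
                                   small[[resp$top_images$image[1]]])
    list(block = block, selection = sel, maps = maps, responses = resp,
         embedding = emb, example_segmentation = seg)
  })

  # -- landscape classification --------------------------------------------
  out$classification <- pipeline_stage("classification", {
    la <- generate_labeled_activations(
      n_images = config$cls_n_images, n_units = config$cls_n_units,
      n_informative = config$cls_n_informative,
      effect_size = config$cls_effect_size,
      seed = derive_seed(seed, 8))
    md <- min_distance_classify(la)
    lda_focal <- loo_lda_classify(la, units = la$informative_units)
    null <- resampling_null(la, la$informative_units,
                            n_iterations = config$n_iterations,
                            seed = derive_seed(seed, 9))
    list(activations = la, min_distance = md, lda_focal = lda_focal,
         resampling = null)
  })

  out$summary <- pipeline_summary(out)
  class(out) <- "navrsa_pipeline"

  if (write_out) {
    jsonlite::write_json(out$summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 12)
    manifest <- list(
      package_version = as.character(utils::packageVersion("navrsa")),
      seed = seed,
      parameters = config[!vapply(config, is.object, logical(1))],
      network = list(input_size = config$network$input_size,
                     channels = config$network$channels,
                     seed = config$network$seed,
                     layer_kinds = vapply(config$network$layers, `[[`,
                                          character(1), "kind")),
      artifacts = list.files(config$out_dir, recursive = TRUE)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 12)
  }
  out
}

pipeline_summary <- function(out) {
  rsa <- out$rsa$group_vs_affordance
  cm <- out$commonality$result
  lmu <- out$slices$lower_minus_upper
  list(
    group_vs_affordance_rho = rsa$statistic,
    group_vs_affordance_se = rsa$bootstrap_se,
    group_vs_affordance_p = rsa$p_value,
    noise_ceiling = out$cohort$noise_ceiling$value,
    best_layer = out$commonality$best_layer,
    best_layer_shared_variance_pct = cm$shared_variance_pct,
    lower_minus_upper_affordance =
      mean(lmu$lower_minus_upper[lmu$target == "affordance"], na.rm = TRUE),
    min_distance_accuracy = out$classification$min_distance$accuracy,
    lda_focal_accuracy = out$classification$lda_focal$accuracy,
    focal_percentile = out$classification$resampling$percentile,
    rf_clusters = out$rf$embedding$k
  )
}

#' @export
print.navrsa_pipeline <- function(x, ...) {
  cat("navrsa pipeline run (", x$config$n_scenes, " scenes, ",
      x$config$n_subjects, " subjects, seed ", x$config$seed, ")\n", sep = "")
  s <- x$summary
  cat(sprintf("  group RDM vs affordance RDM: rho = %.3f (SE %.3f, p = %.4g)\n",
              s$group_vs_affordance_rho, s$group_vs_affordance_se,
              s$group_vs_affordance_p))
  cat(sprintf("  noise ceiling: %.3f\n", s$noise_ceiling))
  cat(sprintf("  shared variance (%s vs affordance in group RDM): %.1f%%\n",
              s$best_layer, s$best_layer_shared_variance_pct))
  cat(sprintf("  slice lower-minus-upper (affordance): %.1f\n",
              s$lower_minus_upper_affordance))
  cat(sprintf("  classification: min-distance %.1f%%, focal LDA %.1f%% (percentile %.1f)\n",
              s$min_distance_accuracy, s$lda_focal_accuracy,
              s$focal_percentile))
  invisible(x)
}
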