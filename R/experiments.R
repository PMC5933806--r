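#' Horizontal-slice occlusion stimuli
#'
#' Everything outside a horizontal slice of the image is masked with a
#' mid-gray occluder; the slice advances down the image by `stride` pixels
#' until the entire vertical axis has been sampled: the regular positions
#' are `floor((H - slice_height) / stride) + 1`, plus one final flush-bottom
#' position when the last regular position does not reach the bottom row.
#' Mid-gray fill minimizes spurious edge energy at the slice borders.
#'
#' @param images image batch (list of grayscale matrices).
#' @param slice_height exposed slice height in pixels (<= image height).
#' @param stride shift between consecutive positions, pixels.
#' @param fill occluder intensity.
#' @return A `slice_stimuli`: list with `positions` (tibble: `position`,
#'   `top`, `bottom`, `center`, `flush_bottom`) and `sets` (one occluded
#'   image list per position).
#' @export
make_slice_stimuli <- function(images, slice_height = 41, stride = 5,
                               fill = 0.5) {
  images <- as_image_list(images)
  h <- nrow(images[[1]])
  abort_if(slice_height > h, "slice_height (", slice_height,
           ") exceeds image height (", h, ")")
  abort_if(stride < 1, "stride must be >= 1")
  tops <- seq(1, by = stride,
              length.out = floor((h - slice_height) / stride) + 1)
  flush <- rep(FALSE, length(tops))
  last_bottom <- tops[length(tops)] + slice_height - 1
  if (last_bottom < h) {
    tops <- c(tops, h - slice_height + 1)
    flush <- c(flush, TRUE)
  }
  positions <- tibble::tibble(
    position = seq_along(tops),
    top = as.integer(tops),
    bottom = as.integer(tops + slice_height - 1),
    center = tops + (slice_height - 1) / 2,
    flush_bottom = flush
  )
  sets <- lapply(tops, function(top) {
    lapply(images, function(img) {
      out <- matrix(fill, nrow(img), ncol(img))
      rows <- top:(top + slice_height - 1)
      out[rows, ] <- img[rows, ]
      out
    })
  })
  structure(list(positions = positions, sets = sets,
                 slice_height = slice_height, stride = stride, fill = fill),
            class = "slice_stimuli")
}

# Layer RDMs for an image set: forward, PCA-reduce (z across components),
# squared-Euclidean RDM. pca_k is capped at each layer's available rank.
layer_rdms <- function(provider, images, labels, pca_k, blocks = NULL) {
  acts <- get_activations(provider, images, blocks)
  lapply(acts, function(a) {
    k <- min(pca_k, nrow(a) - 1, ncol(a))
    scores <- tryCatch(reduce_pca(a, k), error = function(e) NULL)
    if (is.null(scores)) return(NULL)   # degenerate layer (constant patterns)
    compute_rdm(scores, labels = labels)
  })
}

sv_or_na <- function(target, x1, x2) {
  if (is.null(x1) || is.null(x2)) return(NA_real_)
  res <- commonality(target, x1, x2)
  if (res$sv_defined) res$shared_variance_pct else NA_real_
}

#' In-silico input-feature experiment
#'
#' For each stimulus filter, pushes the filtered image set through the
#' network and asks, per layer and per target RDM, what percentage of the
#' layer's explained variance in the target is shared with the filtered
#' stimuli: multiple-regression RSA with X1 = the original-stimuli layer
#' RDM, X2 = the filtered-stimuli layer RDM, followed by commonality
#' variance partitioning.
#'
#' @param images image batch (grayscale matrices, shared condition order
#'   with the targets).
#' @param provider activation provider (mini network or adapter).
#' @param targets named list of target [rdm()]s (e.g. affordance and neural).
#' @param filters filter kinds (see [apply_filter()]).
#' @param pca_k principal components per layer (capped at available rank).
#' @param blocks optional layer subset.
#' @return A `feature_experiment`: list with `table` (tibble: filter, layer,
#'   target, shared_variance_pct) and `summary` (mean and SEM across
#'   layers).
#' @export
run_feature_experiment <- function(images, provider, targets,
                                   filters = c("grayscale", "highpass",
                                               "lowpass", "cardinal",
                                               "oblique"),
                                   pca_k = 45, blocks = NULL) {
  images <- as_image_list(images)
  abort_if(!is.list(targets) || is.null(names(targets)),
           "targets must be a named list of RDMs")
  labels <- rdm_labels(targets[[1]])
  orig <- layer_rdms(provider, images, labels, pca_k, blocks)
  rows <- purrr::map_dfr(filters, function(f) {
    filt_imgs <- lapply(images, apply_filter, kind = f)
    filt <- layer_rdms(provider, filt_imgs, labels, pca_k, blocks)
    purrr::map_dfr(names(orig), function(ly) {
      purrr::map_dfr(names(targets), function(tg) {
        tibble::tibble(
          filter = f, layer = ly, target = tg,
          shared_variance_pct = sv_or_na(targets[[tg]], orig[[ly]], filt[[ly]])
        )
      })
    })
  })
  summary <- rows |>
    dplyr::group_by(.data$filter, .data$target) |>
    dplyr::summarise(
      mean_sv = mean(.data$shared_variance_pct, na.rm = TRUE),
      sem_sv = sd(.data$shared_variance_pct, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$shared_variance_pct))),
      .groups = "drop"
    )
  structure(list(table = rows, summary = summary),
            class = "feature_experiment")
}

#' In-silico slice-occlusion experiment
#'
#' Quantifies the contribution of each vertical image position: for every
#' slice position the occluded stimulus set is forwarded through the
#' network, and the shared variance between the original-stimuli layer RDM
#' (X1) and the occluded-stimuli layer RDM (X2) in each target is computed.
#' Shared-variance values are assigned to all pixels in the slice and
#' averaged across overlapping slices to form a per-row profile, and
#' summarized as the mean over slices whose centers fall in the lower image
#' half minus the upper-half mean.
#'
#' @inheritParams run_feature_experiment
#' @param slice_height,stride,fill see [make_slice_stimuli()].
#' @return A `slice_experiment`: list with `per_slice` (tibble: position,
#'   center, layer, target, shared_variance_pct), `pixel_profile` (tibble:
#'   row, layer, target, shared_variance_pct -- constant across a row, so a
#'   per-row profile), `lower_minus_upper` (tibble per layer x target) and
#'   `positions`.
#' @export
run_slice_experiment <- function(images, provider, targets,
                                 slice_height = 41, stride = 5, fill = 0.5,
                                 pca_k = 45, blocks = NULL) {
  images <- as_image_list(images)
  abort_if(!is.list(targets) || is.null(names(targets)),
           "targets must be a named list of RDMs")
  labels <- rdm_labels(targets[[1]])
  h <- nrow(images[[1]])
  stim <- make_slice_stimuli(images, slice_height, stride, fill)
  orig <- layer_rdms(provider, images, labels, pca_k, blocks)

  per_slice <- purrr::map_dfr(seq_len(nrow(stim$positions)), function(i) {
    occ <- layer_rdms(provider, stim$sets[[i]], labels, pca_k, blocks)
    purrr::map_dfr(names(orig), function(ly) {
      purrr::map_dfr(names(targets), function(tg) {
        tibble::tibble(
          position = i,
          center = stim$positions$center[i],
          layer = ly, target = tg,
          shared_variance_pct = sv_or_na(targets[[tg]], orig[[ly]], occ[[ly]])
        )
      })
    })
  })

  pixel_profile <- purrr::map_dfr(unique(per_slice$layer), function(ly) {
    purrr::map_dfr(names(targets), function(tg) {
      sv <- per_slice$shared_variance_pct[per_slice$layer == ly &
                                            per_slice$target == tg]
      prof <- vapply(seq_len(h), function(r) {
        covering <- stim$positions$top <= r & stim$positions$bottom >= r
        mean(sv[covering], na.rm = TRUE)
      }, numeric(1))
      tibble::tibble(row = seq_len(h), layer = ly, target = tg,
                     shared_variance_pct = prof)
    })
  })

  lower_minus_upper <- per_slice |>
    dplyr::group_by(.data$layer, .data$target) |>
    dplyr::summarise(
      lower_minus_upper =
        mean(.data$shared_variance_pct[.data$center > h / 2], na.rm = TRUE) -
        mean(.data$shared_variance_pct[.data$center <= h / 2], na.rm = TRUE),
      .groups = "drop"
    )

  structure(list(per_slice = per_slice, pixel_profile = pixel_profile,
                 lower_minus_upper = lower_minus_upper,
                 positions = stim$positions),
            class = "slice_experiment")
}
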