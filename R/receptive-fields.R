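#' Occlusion-based discrepancy mapping
#'
#' Characterizes unit selectivity by iteratively occluding the image with a
#' small patch of random pixel values (drawn uniformly over the \[0, 1\]
#' intensity domain, reseeded deterministically from `seed`), forwarding
#' each occluded image, and logging the absolute difference between each
#' unit's activation to the original and to the occluded image. The
#' occluder advances on a regular stride grid:
#' `floor((H - patch) / stride) + 1` positions per axis.
#'
#' @param provider activation provider.
#' @param image a single grayscale image.
#' @param block layer block whose units are mapped.
#' @param units unit indices within the block (default: all units).
#' @param patch_size occluder side length in pixels.
#' @param stride occluder stride in pixels.
#' @param seed integer seed for the occluder values.
#' @return A `discrepancy_map`: list with `discrepancy` (position x unit
#'   matrix of absolute activation differences), `positions` (tibble of
#'   occluder top-left corners), `image_dim`, `patch_size`, `units`.
#' @export
map_discrepancy <- function(provider, image, block, units = NULL,
                            patch_size = 11, stride = 3, seed = 0L) {
  image <- to_grayscale(image)
  h <- nrow(image); w <- ncol(image)
  abort_if(patch_size > h || patch_size > w, "patch does not fit in image")
  a0 <- get_activations(provider, list(image), blocks = block)[[block]]
  n_units <- ncol(a0)
  if (is.null(units)) units <- seq_len(n_units)
  abort_if(any(units < 1 | units > n_units),
           "unit id out of range for block ", block, " (", n_units, " units)")
  rtops <- seq(1, by = stride, length.out = conv_out(h, patch_size, stride))
  ctops <- seq(1, by = stride, length.out = conv_out(w, patch_size, stride))
  positions <- expand.grid(row = rtops, col = ctops)
  patches <- withr::with_seed(seed, {
    lapply(seq_len(nrow(positions)), function(i) {
      matrix(runif(patch_size^2), patch_size, patch_size)
    })
  })
  occluded <- lapply(seq_len(nrow(positions)), function(i) {
    img <- image
    r <- positions$row[i]; cc <- positions$col[i]
    img[r:(r + patch_size - 1), cc:(cc + patch_size - 1)] <- patches[[i]]
    img
  })
  a <- get_activations(provider, occluded, blocks = block)[[block]]
  disc <- abs(sweep(a[, units, drop = FALSE], 2, a0[1, units], "-"))
  structure(list(discrepancy = disc,
                 positions = tibble::as_tibble(positions),
                 image_dim = c(h, w), patch_size = patch_size,
                 stride = stride, units = units, block = block),
            class = "discrepancy_map")
}

#' Pixel-resolution discrepancy map for one unit
#'
#' Each occluder position's discrepancy is assigned to every pixel the
#' occluder covered; overlapping assignments are averaged. Pixels no
#' occluder altered are zero.
#'
#' @param map a [map_discrepancy()] result.
#' @param unit unit id (must be among `map$units`).
#' @return Nonnegative matrix of the image's dimensions.
#' @export
pixel_map <- function(map, unit) {
  stopifnot(inherits(map, "discrepancy_map"))
  j <- match(unit, map$units)
  abort_if(is.na(j), "unit ", unit, " was not mapped")
  h <- map$image_dim[1]; w <- map$image_dim[2]
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  p <- map$patch_size
  for (i in seq_len(nrow(map$positions))) {
    r <- map$positions$row[i]; cc <- map$positions$col[i]
    rows <- r:(r + p - 1); cols <- cc:(cc + p - 1)
    acc[rows, cols] <- acc[rows, cols] + map$discrepancy[i, j]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  out <- acc
  out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  out
}

# 2-D running-mean box filter with edge-renormalized partial windows.
box_smooth <- function(x, size) {
  half_lo <- floor((size - 1) / 2); half_hi <- size - 1 - half_lo
  run1 <- function(m) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    ones <- rbind(0, matrix(cumsum(rep(1, n)), n, ncol(m)))
    lo <- pmax(seq_len(n) - half_lo, 1)
    hi <- pmin(seq_len(n) + half_hi, n)
    (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (ones[hi + 1, , drop = FALSE] - ones[lo, , drop = FALSE])
  }
  t(run1(t(run1(x))))
}

#' Select units by unit-wise RSA
#'
#' Scores every unit by the mean of its unit-wise RSA correlations to an
#' affordance RDM and a neural RDM: the unit's RDM is built from the squared
#' differences of its z-scored activations across images, correlated
#' (Spearman) with each target, and the two correlations averaged.
#' Constant-activation units are scored `NA` and rank last. The top-`n`
#' units by score are selected.
#'
#' @param activations image x unit matrix for one layer.
#' @param affordance_rdm,neural_rdm target [rdm()]s (labels = image order).
#' @param n number of units to select.
#' @return A `unit_selection`: tibble with `unit`, `score`, `rank`,
#'   `selected`.
#' @export
select_units <- function(activations, affordance_rdm, neural_rdm, n = 50) {
  n_units <- ncol(activations)
  abort_if(n > n_units, "cannot select ", n, " of ", n_units, " units")
  va <- rank(rdm_vec(affordance_rdm))
  vn <- rank(rdm_vec(neural_rdm))
  ut <- upper.tri(as.matrix(affordance_rdm))
  scores <- vapply(seq_len(n_units), function(j) {
    z <- activations[, j]
    s <- sd(z)
    if (!is.finite(s) || s < 1e-12) return(NA_real_)
    z <- (z - mean(z)) / s
    d <- outer(z, z, `-`)^2
    vu <- rank(d[ut])
    if (sd(vu) < 1e-12) return(NA_real_)
    mean(c(cor(vu, va), cor(vu, vn)))
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE, na.last = TRUE)
  rk <- integer(n_units); rk[ord] <- seq_len(n_units)
  tibble::tibble(unit = seq_len(n_units), score = scores, rank = rk,
                 selected = rk <= n) |>
    structure(class = c("unit_selection", class(tibble::tibble())))
}

#' Segment a unit's receptive field
#'
#' Smooths the pixel-resolution discrepancy map with a box averaging filter,
#' thresholds at a fraction of the smoothed peak (pixels at least that value
#' are included), and composites a visualization: out-of-mask pixels
#' darkened and the mask boundary outlined. The mask is invariant to
#' positive rescaling of the map; an all-zero map yields a flagged empty
#' mask.
#'
#' @param pixmap pixel-resolution discrepancy matrix (see [pixel_map()]).
#' @param image the underlying grayscale image (for the composite).
#' @param smooth box filter side length in pixels.
#' @param threshold_frac threshold as a fraction of the smoothed peak.
#' @return An `rf_segmentation`: list with `mask` (logical matrix),
#'   `threshold_value`, `outline` (logical matrix), `smoothed`, `peak`
#'   (`c(row, col)` of the smoothed peak; ties broken by lowest row then
#'   lowest column), `composite`, `empty`.
#' @export
segment_receptive_field <- function(pixmap, image = NULL, smooth = 20,
                                    threshold_frac = 0.10) {
  abort_if(length(pixmap) == 0, "empty map")
  sm <- box_smooth(pixmap, smooth)
  pk <- max(sm)
  if (pk <= 0) {
    return(structure(list(mask = matrix(FALSE, nrow(pixmap), ncol(pixmap)),
                          threshold_value = 0, outline = NULL,
                          smoothed = sm, peak = NULL, composite = image,
                          empty = TRUE),
                     class = "rf_segmentation"))
  }
  thr <- threshold_frac * pk
  mask <- sm >= thr
  peak_idx <- which(sm == pk, arr.ind = TRUE)
  peak_idx <- peak_idx[order(peak_idx[, 1], peak_idx[, 2])[1], ]
  outline <- mask & !shrink_mask(mask)
  composite <- if (!is.null(image)) {
    comp <- image
    comp[!mask] <- comp[!mask] * 0.3
    comp[outline] <- 1
    comp
  }
  structure(list(mask = mask, threshold_value = thr, outline = outline,
                 smoothed = sm, peak = c(row = unname(peak_idx[1]),
                                         col = unname(peak_idx[2])),
                 composite = composite, empty = FALSE),
            class = "rf_segmentation")
}

# 4-neighborhood erosion used to trace the mask boundary.
shrink_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  core <- padded[2:(h + 1), 2:(w + 1)]
  core & padded[1:h, 2:(w + 1)] & padded[3:(h + 2), 2:(w + 1)] &
    padded[2:(h + 1), 1:w] & padded[2:(h + 1), 3:(w + 2)]
}

#' Mean response vectors of selected units to their preferred image patches
#'
#' For each selected unit, finds its top images by peak discrepancy,
#' extracts a square patch centered on the smoothed discrepancy peak
#' (clamped to the image), forwards the patches through the network
#' (rescaled to the input size), and averages the response vectors of the
#' requested block across the top images.
#'
#' @param provider activation provider.
#' @param maps list over images of [map_discrepancy()] results (all units of
#'   interest mapped in each).
#' @param images the corresponding image batch.
#' @param units unit ids to characterize.
#' @param block block whose responses are recorded for the patches.
#' @param patch patch side length in pixels.
#' @param top_n number of top images per unit.
#' @param smooth smoothing used when locating the peak.
#' @return A `unit_responses`: list with `responses` (unit x feature
#'   matrix) and `top_images` (tibble: unit, image, peak discrepancy).
#' @export
rf_unit_responses <- function(provider, maps, images, units, block,
                              patch = 81, top_n = 3, smooth = 20) {
  images <- as_image_list(images)
  abort_if(length(maps) != length(images), "one discrepancy map per image")
  peak_disc <- vapply(maps, function(m) {
    apply(m$discrepancy[, match(units, m$units), drop = FALSE], 2, max)
  }, numeric(length(units)))
  peak_disc <- matrix(peak_disc, nrow = length(units))  # unit x image
  abort_if(ncol(peak_disc) < top_n, "need at least ", top_n, " images")
  resp <- NULL; top_tbl <- list()
  for (ui in seq_along(units)) {
    top_imgs <- order(peak_disc[ui, ], decreasing = TRUE)[seq_len(top_n)]
    top_tbl[[ui]] <- tibble::tibble(unit = units[ui], image = top_imgs,
                                    peak = peak_disc[ui, top_imgs])
    patches <- lapply(top_imgs, function(im) {
      pm <- box_smooth(pixel_map(maps[[im]], units[ui]), smooth)
      pk <- which(pm == max(pm), arr.ind = TRUE)
      pk <- pk[order(pk[, 1], pk[, 2])[1], ]
      extract_patch(images[[im]], pk[1], pk[2], patch)
    })
    a <- get_activations(provider, patches, blocks = block)[[block]]
    v <- colMeans(a)
    if (is.null(resp)) resp <- matrix(0, length(units), length(v))
    resp[ui, ] <- v
  }
  rownames(resp) <- paste0("u", units)
  structure(list(responses = resp, top_images = dplyr::bind_rows(top_tbl),
                 units = units, block = block),
            class = "unit_responses")
}

# Square patch centered at (row, col), clamped inside the image.
extract_patch <- function(image, row, col, size) {
  h <- nrow(image); w <- ncol(image)
  size <- min(size, h, w)
  r0 <- min(max(1, row - floor(size / 2)), h - size + 1)
  c0 <- min(max(1, col - floor(size / 2)), w - size + 1)
  image[r0:(r0 + size - 1), c0:(c0 + size - 1)]
}

#' Embed and cluster unit selectivity profiles
#'
#' Embeds the unit response matrix into two dimensions with t-distributed
#' stochastic neighbor embedding (perplexity `min(15, (n_units - 1) / 3)`)
#' and partitions the embedding with k-means (20 restarts), choosing the
#' number of clusters over `k_range` by the mean silhouette criterion; if
#' the best silhouette is below `min_silhouette` a single cluster is
#' reported. Identical unit responses make the embedding degenerate; the
#' result is then flagged and all units share one cluster.
#'
#' @param responses unit x feature matrix (or a `unit_responses`).
#' @param k_range candidate cluster counts (values >= 2).
#' @param min_silhouette silhouette floor below which k = 1 is chosen.
#' @param seed integer seed (t-SNE and k-means are seeded).
#' @return A `unit_embedding`: list with `embedding` (tibble: unit, x, y,
#'   cluster), `k`, `silhouette` (tibble per candidate k), `degenerate`.
#' @export
embed_and_cluster_units <- function(responses, k_range = 2:10,
                                    min_silhouette = 0.25, seed = 0L) {
  if (inherits(responses, "unit_responses")) responses <- responses$responses
  n <- nrow(responses)
  abort_if(n < 4, "need at least 4 units")
  k_range <- k_range[k_range >= 2 & k_range < n]
  abort_if(length(k_range) == 0, "fewer units than the smallest cluster count")
  if (max(apply(responses, 2, sd)) < 1e-12) {
    emb <- tibble::tibble(unit = rownames(responses) %||% seq_len(n),
                          x = 0, y = 0, cluster = 1L)
    return(structure(list(embedding = emb, k = 1L, silhouette = NULL,
                          degenerate = TRUE),
                     class = "unit_embedding"))
  }
  perplexity <- min(15, (n - 1) / 3)
  xy <- withr::with_seed(seed, {
    Rtsne::Rtsne(responses, dims = 2, perplexity = perplexity,
                 pca = FALSE, check_duplicates = FALSE,
                 max_iter = 500, verbose = FALSE)$Y
  })
  dmat <- dist(xy)
  fits <- withr::with_seed(derive_seed(seed, 1), {
    lapply(k_range, function(k) {
      km <- kmeans(xy, centers = k, nstart = 20, iter.max = 50)
      list(k = k, cluster = km$cluster,
           silhouette = mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"]))
    })
  })
  sil <- tibble::tibble(k = vapply(fits, `[[`, numeric(1), "k"),
                        silhouette = vapply(fits, `[[`, numeric(1), "silhouette"))
  best_i <- which.max(sil$silhouette)
  if (sil$silhouette[best_i] < min_silhouette) {
    clusters <- rep(1L, n); best <- 1L
  } else {
    best <- sil$k[best_i]
    clusters <- fits[[best_i]]$cluster
  }
  emb <- tibble::tibble(unit = rownames(responses) %||% seq_len(n),
                        x = xy[, 1], y = xy[, 2], cluster = clusters)
  structure(list(embedding = emb, k = as.integer(best), silhouette = sil,
                 degenerate = FALSE),
            class = "unit_embedding")
}
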