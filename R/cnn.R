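#' Layer specifications for the mini convolutional network
#'
#' The network is a sequence of linear-nonlinear operations: valid
#' convolution, rectification (`max(0, x)`), local max pooling (only the
#' maximum activation in each pool survives), local response normalization
#' across a channel neighborhood (`b = a / (k + alpha * sum a^2)^beta`),
#' and dense (fully connected) layers. A new named block starts at every
#' convolution or dense layer; the recorded activations of a block are the
#' final outputs of its linear-nonlinear chain.
#'
#' @param n_filters,kernel_size,stride convolution geometry.
#' @param pool_size,pool_stride max-pool geometry.
#' @param k,alpha,beta,n local-normalization constants (defaults are the
#'   standard values of the architecture family this emulates: k = 2,
#'   alpha = 1e-4, beta = 0.75, channel neighborhood n = 5).
#' @param n_units dense layer width.
#' @return A `layer_spec` list.
#' @name layer_specs
NULL

#' @rdname layer_specs
#' @export
conv_spec <- function(n_filters, kernel_size, stride = 1) {
  abort_if(kernel_size < 1 || stride < 1, "kernel size and stride must be >= 1")
  structure(list(kind = "convolution", n_filters = n_filters,
                 kernel_size = kernel_size, stride = stride),
            class = "layer_spec")
}

#' @rdname layer_specs
#' @export
relu_spec <- function() structure(list(kind = "rectification"), class = "layer_spec")

#' @rdname layer_specs
#' @export
max_pool_spec <- function(pool_size = 2, pool_stride = pool_size) {
  abort_if(pool_size < 1 || pool_stride < 1, "pool size and stride must be >= 1")
  structure(list(kind = "max_pool", pool_size = pool_size,
                 pool_stride = pool_stride), class = "layer_spec")
}

#' @rdname layer_specs
#' @export
local_norm_spec <- function(k = 2, alpha = 1e-4, beta = 0.75, n = 5) {
  structure(list(kind = "local_norm", k = k, alpha = alpha, beta = beta,
                 n = n), class = "layer_spec")
}

#' @rdname layer_specs
#' @export
dense_spec <- function(n_units) {
  abort_if(n_units < 1, "n_units must be >= 1")
  structure(list(kind = "dense", n_units = n_units), class = "layer_spec")
}

#' Default desk-scale architecture
#'
#' Three convolution(+rectification) blocks -- the first two followed by max
#' pooling and local normalization -- and one dense block, preserving the
#' convolution / rectification / pooling / normalization hierarchy that the
#' in-silico experiments probe while evaluating in milliseconds.
#'
#' @return List of [layer_specs].
#' @export
default_layers <- function() {
  list(
    conv_spec(8, 5, stride = 2), relu_spec(), max_pool_spec(2, 2), local_norm_spec(),
    conv_spec(16, 3, stride = 1), relu_spec(), max_pool_spec(2, 2), local_norm_spec(),
    conv_spec(32, 3, stride = 1), relu_spec(),
    dense_spec(64)
  )
}

#' Network configuration
#'
#' @param input_size `c(height, width)` expected by the network; inputs of a
#'   different size are rescaled with bilinear interpolation before forward
#'   evaluation.
#' @param channels 1 (grayscale) or 3.
#' @param layers ordered list of [layer_specs].
#' @param seed integer seed for weight initialization.
#' @return A `network_config`.
#' @export
network_config <- function(input_size = c(64, 64), channels = 1,
                           layers = default_layers(), seed = 42L) {
  abort_if(!channels %in% c(1, 3), "channels must be 1 or 3")
  structure(list(input_size = as.integer(input_size), channels = channels,
                 layers = layers, seed = as.integer(seed)),
            class = "network_config")
}

conv_out <- function(size, k, stride) floor((size - k) / stride) + 1

# Walk the layer stack computing spatial shapes; errors on spatial collapse.
trace_shapes <- function(config) {
  h <- config$input_size[1]; w <- config$input_size[2]; ch <- config$channels
  shapes <- vector("list", length(config$layers))
  for (i in seq_along(config$layers)) {
    l <- config$layers[[i]]
    if (l$kind == "convolution") {
      h2 <- conv_out(h, l$kernel_size, l$stride)
      w2 <- conv_out(w, l$kernel_size, l$stride)
      abort_if(h2 < 1 || w2 < 1,
               "layer ", i, " (convolution) collapses the spatial dimensions")
      h <- h2; w <- w2; ch <- l$n_filters
    } else if (l$kind == "max_pool") {
      h2 <- conv_out(h, l$pool_size, l$pool_stride)
      w2 <- conv_out(w, l$pool_size, l$pool_stride)
      abort_if(h2 < 1 || w2 < 1,
               "layer ", i, " (max_pool) collapses the spatial dimensions")
      h <- h2; w <- w2
    } else if (l$kind == "dense") {
      shapes[[i]] <- c(units = l$n_units, in_dim = h * w * ch)
      h <- 1; w <- 1; ch <- l$n_units
      next
    }
    shapes[[i]] <- c(h = h, w = w, ch = ch)
  }
  shapes
}

float32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4L,
                                        endian = "little"),
                               numeric(), n = length(x), size = 4L,
                               endian = "little")

#' Build a mini convolutional network
#'
#' Weights are initialized from a seeded Gaussian scaled by `1 / sqrt(fan-in)`
#' (biases zero) and quantized to float32, the precision of the on-disk
#' weight store, so a save/load round trip reproduces activations bit
#' exactly.
#'
#' @param config a [network_config()].
#' @return A `mini_cnn` with `$config`, `$weights`, `$blocks` (block name per
#'   layer) and `$shapes`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  shapes <- trace_shapes(config)
  blocks <- character(length(config$layers))
  conv_i <- 0L; dense_i <- 0L; current <- ""
  in_ch <- config$channels
  hw <- config$input_size
  weights <- vector("list", length(config$layers))
  withr::with_seed(config$seed, {
    for (i in seq_along(config$layers)) {
      l <- config$layers[[i]]
      if (l$kind == "convolution") {
        conv_i <- conv_i + 1L
        current <- paste0("conv", conv_i)
        fan_in <- l$kernel_size^2 * in_ch
        W <- matrix(rnorm(fan_in * l$n_filters) / sqrt(fan_in),
                    fan_in, l$n_filters)
        weights[[i]] <- list(W = matrix(float32(W), nrow(W)),
                             b = rep(0, l$n_filters))
        in_ch <- l$n_filters
      } else if (l$kind == "dense") {
        dense_i <- dense_i + 1L
        current <- paste0("dense", dense_i)
        fan_in <- shapes[[i]][["in_dim"]]
        W <- matrix(rnorm(fan_in * l$n_units) / sqrt(fan_in),
                    fan_in, l$n_units)
        weights[[i]] <- list(W = matrix(float32(W), nrow(W)),
                             b = rep(0, l$n_units))
      }
      blocks[i] <- current
    }
  })
  structure(list(config = config, weights = weights, blocks = blocks,
                 shapes = shapes),
            class = c("mini_cnn", "activation_provider"))
}

# ---- forward primitives ------------------------------------------------

# Gather index matrix for valid convolution/pooling windows.
im2col_index <- function(h, w, ch, k, stride) {
  oh <- conv_out(h, k, stride); ow <- conv_out(w, k, stride)
  r0 <- rep(seq(1, by = stride, length.out = oh), times = ow)
  c0 <- rep(seq(1, by = stride, length.out = ow), each = oh)
  dr <- rep(rep(0:(k - 1), times = k), times = ch)
  dc <- rep(rep(0:(k - 1), each = k), times = ch)
  dch <- rep(0:(ch - 1), each = k * k)
  pos <- (c0 - 1) * h + r0                       # linear index of window origin
  off <- dc * h + dr + dch * h * w
  list(idx = outer(pos, off, `+`), oh = oh, ow = ow)
}

# Index caching: gather matrices depend only on layer geometry, which is
# fixed once inputs are rescaled to the configured size, so a forward call
# computes them once and reuses them across the image batch.
cached_index <- function(cache, key, h, w, ch, k, stride) {
  if (is.null(cache[[key]])) cache[[key]] <- im2col_index(h, w, ch, k, stride)
  cache[[key]]
}

conv_forward <- function(x, wts, k, stride, cache, key) {
  d <- dim(x)
  ii <- cached_index(cache, key, d[1], d[2], d[3], k, stride)
  P <- matrix(x[ii$idx], nrow(ii$idx))
  out <- P %*% wts$W
  if (any(wts$b != 0)) out <- sweep(out, 2, wts$b, "+")
  array(out, c(ii$oh, ii$ow, ncol(wts$W)))
}

pool_forward <- function(x, pool, stride, cache, key) {
  d <- dim(x)
  ii <- cached_index(cache, key, d[1], d[2], d[3], pool, stride)
  P <- matrix(x[ii$idx], nrow(ii$idx))   # positions x (pool^2 * C)
  p2 <- pool * pool
  out <- matrix(0, nrow(P), d[3])
  for (ch in seq_len(d[3])) {
    block <- (ch - 1) * p2
    m <- P[, block + 1]
    for (j in 2:p2) m <- pmax(m, P[, block + j])
    out[, ch] <- m
  }
  array(out, c(ii$oh, ii$ow, d[3]))
}

local_norm_forward <- function(x, k, alpha, beta, n) {
  d <- dim(x); C <- d[3]
  half <- floor(n / 2)
  sq <- x^2
  # cumulative channel sums -> windowed sums by subtraction
  cum <- array(0, c(d[1], d[2], C + 1))
  for (ch in seq_len(C)) cum[, , ch + 1] <- cum[, , ch] + sq[, , ch]
  out <- x
  for (ch in seq_len(C)) {
    lo <- max(1, ch - half); hi <- min(C, ch + half)
    s <- cum[, , hi + 1] - cum[, , lo]
    out[, , ch] <- x[, , ch] / (k + alpha * s)^beta
  }
  out
}

as_input_array <- function(img, config) {
  if (length(dim(img)) == 2L) img <- array(as.numeric(img), c(dim(img), 1L))
  abort_if(dim(img)[3] != config$channels,
           "channel mismatch: image has ", dim(img)[3], ", network expects ",
           config$channels)
  if (!all(dim(img)[1:2] == config$input_size)) {
    img <- resize_bilinear(img, config$input_size[1], config$input_size[2])
    if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  }
  img
}

#' Forward-propagate images through the network
#'
#' Runs each image through the layer stack and records, for every named
#' block, the final output of that block's linear-nonlinear chain. Images
#' whose size differs from the configured input size are rescaled with
#' bilinear interpolation first.
#'
#' @param network a `mini_cnn`.
#' @param images a single image, a list of images, or an `H x W x n` array
#'   of grayscale images.
#' @return An `activation_set`: named list of image x unit matrices, each
#'   carrying a `spatial` attribute `c(h, w, channels)` for convolutional
#'   blocks.
#' @export
forward <- function(network, images) {
  stopifnot(inherits(network, "mini_cnn"))
  images <- as_image_list(images)
  block_names <- unique(network$blocks[network$blocks != ""])
  acts <- setNames(vector("list", length(block_names)), block_names)
  cache <- new.env(parent = emptyenv())
  for (ix in seq_along(images)) {
    x <- as_input_array(images[[ix]], network$config)
    layers <- network$config$layers
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      key <- as.character(i)
      x <- switch(l$kind,
        convolution = conv_forward(x, network$weights[[i]], l$kernel_size,
                                   l$stride, cache, key),
        rectification = pmax(x, 0),
        max_pool = pool_forward(x, l$pool_size, l$pool_stride, cache, key),
        local_norm = local_norm_forward(x, l$k, l$alpha, l$beta, l$n),
        dense = {
          v <- drop(crossprod(network$weights[[i]]$W, as.vector(x))) +
            network$weights[[i]]$b
          array(v, c(1, 1, length(v)))
        })
      blk <- network$blocks[i]
      last_of_block <- i == length(layers) || network$blocks[i + 1] != blk
      if (last_of_block && blk != "") {
        flat <- as.vector(x)
        if (is.null(acts[[blk]])) {
          acts[[blk]] <- matrix(0, length(images), length(flat))
          attr(acts[[blk]], "spatial") <- dim(x)
        }
        acts[[blk]][ix, ] <- flat
      }
    }
  }
  structure(acts, class = "activation_set")
}

as_image_list <- function(images) {
  if (is_image(images) && !is.list(images)) {
    if (length(dim(images)) == 3L && dim(images)[3] > 3) {
      return(lapply(seq_len(dim(images)[3]), function(i) images[, , i]))
    }
    return(list(images))
  }
  abort_if(!is.list(images) || !all(vapply(images, is_image, logical(1))),
           "images must be matrices/arrays or a list of them")
  images
}

#' Spatial view of a convolutional block's activations
#'
#' @param activations an `activation_set` from [forward()].
#' @param block block name, e.g. `"conv2"`.
#' @param image image index.
#' @return `h x w x channels` array holding the same values as the
#'   flattened row.
#' @export
spatial_view <- function(activations, block, image = 1) {
  a <- activations[[block]]
  abort_if(is.null(a), "no block named ", block)
  array(a[image, ], attr(a, "spatial"))
}

# ---- weight persistence ------------------------------------------------

#' Save and load network weights
#'
#' The weight store is a JSON manifest (layer index, kind, shapes, dtype,
#' byte offsets) plus a little-endian float32 binary blob. Because weights
#' are float32-quantized at build time, a save/load round trip reproduces
#' forward activations bit exactly.
#'
#' @param network a `mini_cnn`.
#' @param path directory to hold `manifest.json` and `weights.bin`.
#' @return `save_weights()`: `path` invisibly. `load_weights()`: a
#'   `mini_cnn`.
#' @export
save_weights <- function(network, path) {
  stopifnot(inherits(network, "mini_cnn"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- list(); blob <- numeric(0)
  for (i in seq_along(network$weights)) {
    wt <- network$weights[[i]]
    if (is.null(wt)) next
    entries[[length(entries) + 1]] <- list(
      layer = i, kind = network$config$layers[[i]]$kind,
      w_shape = dim(wt$W), b_length = length(wt$b),
      dtype = "float32", offset = length(blob)
    )
    blob <- c(blob, as.vector(wt$W), wt$b)
  }
  manifest <- list(
    input_size = network$config$input_size,
    channels = network$config$channels,
    n_layers = length(network$config$layers),
    layer_kinds = vapply(network$config$layers, `[[`, character(1), "kind"),
    entries = entries, total = length(blob)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(blob, con, size = 4L, endian = "little")
  invisible(path)
}

#' @param config a [network_config()] whose layer shapes must match the
#'   stored manifest.
#' @rdname save_weights
#' @export
load_weights <- function(config, path) {
  mf <- tryCatch(
    jsonlite::read_json(file.path(path, "manifest.json"), simplifyVector = TRUE),
    error = function(e) stop("corrupted manifest: ", conditionMessage(e),
                             call. = FALSE))
  abort_if(is.null(mf$entries) || is.null(mf$total), "corrupted manifest")
  abort_if(mf$n_layers != length(config$layers),
           "layer count mismatch: manifest has ", mf$n_layers,
           ", config has ", length(config$layers))
  net <- build_network(config)
  blob <- readBin(file.path(path, "weights.bin"), numeric(),
                  n = mf$total, size = 4L, endian = "little")
  entries <- mf$entries
  for (j in seq_len(nrow(entries))) {
    i <- entries$layer[j]
    shape <- unlist(entries$w_shape[j])
    have <- dim(net$weights[[i]]$W)
    abort_if(!identical(as.integer(shape), as.integer(have)),
             "shape mismatch at layer ", i, ": expected ",
             paste(have, collapse = "x"), ", found ",
             paste(shape, collapse = "x"))
    off <- entries$offset[j]
    nw <- prod(shape); nb <- entries$b_length[j]
    net$weights[[i]]$W <- matrix(blob[off + seq_len(nw)], shape[1], shape[2])
    net$weights[[i]]$b <- blob[off + nw + seq_len(nb)]
  }
  net
}

# ---- adapter contract --------------------------------------------------

#' Wrap an arbitrary activation source as a provider
#'
#' Any function mapping an image batch (list of images) to a named list of
#' image x unit activation matrices can stand in for the mini network in
#' every in-silico experiment -- this is how activations of an external,
#' pre-trained model would be plugged in.
#'
#' @param fn `function(images) -> named list of matrices`.
#' @return An `activation_provider`.
#' @export
activation_adapter <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = c("activation_adapter", "activation_provider"))
}

#' Get activations from any provider
#'
#' @param provider a `mini_cnn` or [activation_adapter()].
#' @param images image batch.
#' @param blocks optional character vector restricting the returned blocks.
#' @return Named list of image x unit matrices.
#' @export
get_activations <- function(provider, images, blocks = NULL) {
  acts <- if (inherits(provider, "mini_cnn")) {
    forward(provider, images)
  } else if (inherits(provider, "activation_adapter")) {
    out <- provider$fn(as_image_list(images))
    abort_if(!is.list(out) || is.null(names(out)),
             "adapter must return a named list of matrices")
    out
  } else {
    stop("not an activation provider", call. = FALSE)
  }
  if (!is.null(blocks)) {
    missing <- setdiff(blocks, names(acts))
    abort_if(length(missing) > 0, "unknown block(s): ",
             paste(missing, collapse = ", "))
    acts <- acts[blocks]
  }
  acts
}
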