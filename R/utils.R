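# Internal helpers shared across modules.

# Deterministic child seed derivation; keeps results < 2^31 so they remain
# valid R integers when passed on to set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(offset)) %% 2147483629)
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# z-score columns with the sample (n - 1) denominator; constant columns are
# reported back to the caller via the "dropped" attribute when drop = TRUE.
zscore_cols <- function(x, drop = FALSE, tol = 1e-12) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (drop && any(s < tol)) {
    keep <- s >= tol
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]
    s <- s[keep]
    out <- sweep(sweep(x, 2, mu), 2, s, "/")
    attr(out, "dropped") <- sum(!keep)
    return(out)
  }
  abort_if(any(s < tol), "cannot z-score: ", sum(s < tol), " constant feature(s)")
  out <- sweep(sweep(x, 2, mu), 2, s, "/")
  attr(out, "dropped") <- 0L
  out
}

zscore_rows <- function(x, tol = 1e-12) {
  t(zscore_cols(t(x), tol = tol))
}

# z-score a vector; degenerate (constant) input maps to all zeros with a flag.
zscore_vec <- function(v, tol = 1e-12) {
  s <- sd(v)
  if (!is.finite(s) || s < tol) {
    out <- rep(0, length(v))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (v - mean(v)) / s
  attr(out, "degenerate") <- FALSE
  out
}

# Classed matrices (scene_image, path_heat_map) fail is.matrix(), so all
# image checks go by the dim attribute.
is_mat2 <- function(x) is.numeric(x) && length(dim(x)) == 2L

is_image <- function(x) {
  is.numeric(x) && length(dim(x)) %in% c(2L, 3L)
}

image_dims <- function(x) dim(x)[1:2]

# Bilinear rescale of a grayscale matrix (or HxWxC array, per channel).
resize_bilinear <- function(x, height, width) {
  if (length(dim(x)) == 3L) {
    out <- array(0, dim = c(height, width, dim(x)[3]))
    for (ch in seq_len(dim(x)[3])) {
      out[, , ch] <- resize_bilinear(x[, , ch], height, width)
    }
    return(out)
  }
  if (all(dim(x) == c(height, width))) return(x)
  x <- matrix(as.numeric(x), nrow(x))  # drop image classes for S4 dispatch
  # EBImage uses an x (column) major layout, hence the transposes.
  m <- EBImage::imageData(EBImage::resize(
    EBImage::Image(t(x)), w = width, h = height, filter = "bilinear"
  ))
  t(m)
}

# Mean of x plus/minus the standard error across grouping.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sem = sd(x) / sqrt(length(x)))
}
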