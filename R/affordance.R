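#' Bin a path heat map into a 180-bin angular histogram
#'
#' Sums heat-map values along one-degree angular bins radiating from the
#' bottom-center origin. Bin `k` (k = 0..179) covers angles `[k, k + 1)`
#' degrees, with 0 degrees pointing right, 90 straight ahead. Every pixel
#' above the origin row contributes its value to the bin of its angle
#' `atan2(rows above origin, columns right of origin)`; pixels on the origin
#' row contribute to bin 0 or 179 by their horizontal sign, and the origin
#' pixel itself is excluded. Total histogram mass therefore equals the map's
#' mass over the upper half-plane.
#'
#' @param map a `path_heat_map` (or any nonnegative matrix; the origin then
#'   defaults to the bottom-center pixel).
#' @return Numeric vector of length 180, named by bin start angle (0:179).
#' @export
bin_paths <- function(map) {
  abort_if(any(map < 0), "heat map must be nonnegative")
  abort_if(sum(map) <= 0, "heat map has zero mass")
  h <- nrow(map); w <- ncol(map)
  origin <- attr(map, "origin")
  if (is.null(origin)) origin <- c(row = h, col = floor(w / 2) + 1)
  orow <- origin[["row"]]; ocol <- origin[["col"]]

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- orow - rows
  dx <- cols - ocol
  ang <- atan2(dy, dx) * 180 / pi
  bin <- floor(ang)                      # 0..179 for dy > 0
  bin[dy == 0 & dx > 0] <- 0             # origin row, rightward
  bin[dy == 0 & dx < 0] <- 179           # origin row, leftward
  keep <- (dy > 0 | (dy == 0 & dx != 0)) & bin >= 0 & bin <= 179
  hist <- rep(0, 180)
  agg <- rowsum(as.numeric(map[keep]), group = bin[keep])
  hist[as.integer(rownames(agg)) + 1] <- agg[, 1]
  names(hist) <- 0:179
  hist
}

# Orthonormal DCT-II basis (n x n).
dct_basis <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

#' Penalized discrete-cosine smoothing with GCV-selected penalty
#'
#' Automatic smoothing of equally spaced data by penalized least squares in
#' the discrete cosine basis: the smoothed signal is
#' `IDCT(G * DCT(y))` with `G = 1 / (1 + s * lambda^2)`, where `lambda` are
#' the eigenvalues of the second-difference operator under reflective
#' boundary conditions and the penalty `s` is selected by generalized cross
#' validation over a 61-point log grid spanning 1e-6 to 1e6.
#'
#' @param y numeric vector of finite values.
#' @param penalty_grid candidate penalties (default the grid above).
#' @return Smoothed vector with attributes `penalty` (chosen `s`) and `gcv`.
#' @export
dct_smooth <- function(y, penalty_grid = 10^seq(-6, 6, length.out = 61)) {
  abort_if(!all(is.finite(y)), "input must be finite")
  n <- length(y)
  C <- dct_basis(n)
  dy <- drop(C %*% y)
  lam2 <- (2 - 2 * cos((0:(n - 1)) * pi / n))^2
  gcv <- vapply(penalty_grid, function(s) {
    g <- 1 / (1 + s * lam2)
    rss <- sum(((1 - g) * dy)^2)
    trh <- sum(g)
    n * rss / (n - trh)^2
  }, numeric(1))
  s <- penalty_grid[which.min(gcv)]
  g <- 1 / (1 + s * lam2)
  out <- drop(crossprod(C, g * dy))
  attributes(out) <- NULL
  names(out) <- names(y)
  attr(out, "penalty") <- s
  attr(out, "gcv") <- min(gcv)
  out
}

#' Build a navigational-affordance histogram from a path heat map
#'
#' The three-stage affordance representation: raw one-degree angular
#' histogram (see [bin_paths()]), automatic discrete-cosine smoothing
#' ([dct_smooth()]), and z-scoring across the 180 angular bins. A constant
#' smoothed histogram cannot be z-scored; it is encoded as all zeros and
#' flagged `degenerate` so downstream RDM computation stays total.
#'
#' @param map a `path_heat_map`, or a numeric length-180 raw histogram.
#' @return An `affordance_histogram`: tibble with columns `bin_deg`, `raw`,
#'   `smoothed`, `normalized`; attributes `degenerate` and `penalty`.
#' @export
affordance_histogram <- function(map) {
  raw <- if (length(dim(map)) == 2L) bin_paths(map) else {
    abort_if(length(map) != 180, "raw histogram must have 180 bins")
    abort_if(!all(is.finite(map)), "raw histogram must be finite")
    map
  }
  smoothed <- dct_smooth(as.numeric(raw))
  normalized <- zscore_vec(as.numeric(smoothed))
  out <- tibble::tibble(
    bin_deg = 0:179,
    raw = as.numeric(raw),
    smoothed = as.numeric(smoothed),
    normalized = as.numeric(normalized)
  )
  attr(out, "degenerate") <- isTRUE(attr(normalized, "degenerate"))
  attr(out, "penalty") <- attr(smoothed, "penalty")
  class(out) <- c("affordance_histogram", class(out))
  out
}

#' Stack affordance histograms into a pattern matrix
#'
#' @param histograms list of [affordance_histogram()] objects.
#' @param column which representation to stack (default `"normalized"`).
#' @return Condition x bin matrix suitable for [compute_rdm()].
#' @export
affordance_patterns <- function(histograms, column = "normalized") {
  m <- do.call(rbind, lapply(histograms, function(hh) hh[[column]]))
  rownames(m) <- names(histograms) %||% paste0("scene", seq_along(histograms))
  colnames(m) <- paste0("deg", 0:179)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
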