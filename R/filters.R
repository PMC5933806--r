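#' Convert an image to grayscale
#'
#' RGB(A) arrays are reduced with the standard luma weights
#' (0.299, 0.587, 0.114); grayscale matrices pass through unchanged, so the
#' conversion is idempotent.
#'
#' @param image matrix or `H x W x {3,4}` array in \[0, 1\].
#' @return Numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (is_mat2(image)) return(image)
  d <- dim(image)
  abort_if(length(d) != 3L || d[3] < 3, "expected a matrix or an RGB(A) array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Centered frequency grid in cycles/pixel along one axis.
freq_axis <- function(n) (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n

#' Fourier-domain Gaussian frequency filtering
#'
#' The image spectrum is multiplied by an isotropic Gaussian transfer
#' function `G(f) = exp(-f^2 / (2 sigma^2))` (`sigma` in cycles/pixel) for
#' low-pass filtering, or by its complement `1 - G` for high-pass filtering
#' (the only reading that removes low frequencies, including the mean).
#' The two transfer functions built from the same `sigma` sum to one at
#' every frequency.
#'
#' @param image grayscale matrix.
#' @param sigma_cpp Gaussian SD in cycles/pixel (> 0).
#' @param pass `"low"` or `"high"`.
#' @return Filtered matrix (imaginary residue below 1e-9 discarded).
#' @export
fourier_filter <- function(image, sigma_cpp, pass = c("low", "high")) {
  pass <- match.arg(pass)
  abort_if(!is_mat2(image), "frequency filters need a 2-D grayscale image")
  abort_if(sigma_cpp <= 0, "sigma_cpp must be positive")
  h <- nrow(image); w <- ncol(image)
  f2 <- outer(freq_axis(h)^2, freq_axis(w)^2, `+`)
  G <- exp(-f2 / (2 * sigma_cpp^2))
  if (pass == "high") G <- 1 - G
  out <- fft(fft(image) * G, inverse = TRUE) / (h * w)
  Re(out)
}

orientation_kernels <- function(set = c("cardinal", "oblique")) {
  set <- match.arg(set)
  if (set == "cardinal") {
    horizontal <- matrix(c(-1, 2, -1, -1, 2, -1, -1, 2, -1), 3, 3)
    list(horizontal, t(horizontal))
  } else {
    diag1 <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3)
    list(diag1, diag1[, 3:1])
  }
}

conv3x3 <- function(image, kernel) {
  # strip any image class so EBImage's S4 dispatch sees a plain matrix
  m <- matrix(as.numeric(image), nrow(image))
  EBImage::imageData(EBImage::filter2(t(m), t(kernel),
                                      boundary = "replicate"))
}

#' Oriented contour energy
#'
#' Convolves the grayscale image with the two 3x3 zero-sum line-detection
#' kernels of the requested orientation set (cardinal: 0 and 90 degrees;
#' oblique: 45 and 135 degrees), then combines them by squaring, summing and
#' taking the square root.
#'
#' @param image grayscale matrix.
#' @param set `"cardinal"` or `"oblique"`.
#' @return Nonnegative energy matrix.
#' @export
orientation_energy <- function(image, set = c("cardinal", "oblique")) {
  set <- match.arg(set)
  image <- to_grayscale(image)
  ks <- orientation_kernels(set)
  c1 <- conv3x3(image, ks[[1]])
  c2 <- conv3x3(image, ks[[2]])
  t(sqrt(c1^2 + c2^2))
}

#' Apply a named stimulus filter
#'
#' The five stimulus transformations of the input-feature experiments:
#' grayscale conversion, high-pass (Gaussian SD 0.1 cycles/pixel) and
#' low-pass (SD 0.0075 cycles/pixel) Fourier filtering, and cardinal or
#' oblique contour-energy extraction. Grayscale conversion precedes every
#' frequency or orientation filter.
#'
#' @param image matrix or RGB array.
#' @param kind one of `"grayscale"`, `"highpass"`, `"lowpass"`,
#'   `"cardinal"`, `"oblique"`.
#' @param sigma_cpp override of the Gaussian SD for frequency filters.
#' @return Filtered grayscale matrix.
#' @export
apply_filter <- function(image,
                         kind = c("grayscale", "highpass", "lowpass",
                                  "cardinal", "oblique"),
                         sigma_cpp = NULL) {
  kind <- match.arg(kind)
  g <- to_grayscale(image)
  switch(kind,
    grayscale = g,
    highpass = fourier_filter(g, sigma_cpp %||% 0.1, "high"),
    lowpass = fourier_filter(g, sigma_cpp %||% 0.0075, "low"),
    cardinal = orientation_energy(g, "cardinal"),
    oblique = orientation_energy(g, "oblique")
  )
}
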