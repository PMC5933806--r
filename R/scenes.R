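#' Specify a parametric indoor scene
#'
#' A scene is a single-vanishing-point indoor view seen from the bottom
#' center of the image: a textured floor plane, a wall plane, a dark
#' floor--wall junction row, bright door-like openings on the wall at given
#' azimuths, and brighter walkable path wedges on the floor leading from the
#' viewer's position toward each opening. Azimuths follow the angular
#' convention used throughout the package: angles are measured from the
#' bottom-center origin with 0 degrees pointing right, 90 degrees straight
#' ahead (up the image), approaching 180 degrees pointing left.
#'
#' @param image_size integer vector `c(height, width)` in pixels. Odd widths
#'   make the left--right mirror of a scene exactly equal to the scene of the
#'   mirrored specification.
#' @param opening_azimuths numeric vector of door azimuths in degrees,
#'   strictly within (0, 180).
#' @param opening_widths angular widths of the openings in degrees (recycled).
#' @param wall_luminance,floor_luminance base intensities in \[0, 1\].
#' @param texture_frequency sinusoidal texture frequency in cycles/pixel.
#' @param door_luminance intensity of the door rectangles; set equal to
#'   `wall_luminance` to suppress wall-borne affordance cues.
#' @param path_contrast added intensity of the floor path wedges; set to 0 to
#'   suppress floor-borne affordance cues.
#' @param horizon_frac fraction of the image height at which the floor--wall
#'   junction row sits (measured from the top).
#' @param seed integer seed (kept for interface uniformity; rendering is
#'   fully deterministic).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(227, 227),
                       opening_azimuths = 90,
                       opening_widths = 14,
                       wall_luminance = 0.45,
                       floor_luminance = 0.30,
                       texture_frequency = 0.05,
                       door_luminance = 0.90,
                       path_contrast = 0.15,
                       horizon_frac = 0.55,
                       seed = 1L) {
  abort_if(length(image_size) != 2 || any(image_size < 16),
           "image_size must be c(height, width), each >= 16")
  abort_if(length(opening_azimuths) < 1, "at least one opening azimuth is required")
  abort_if(any(opening_azimuths <= 0 | opening_azimuths >= 180),
           "opening azimuths must lie strictly within (0, 180) degrees")
  abort_if(any(opening_widths <= 0), "opening widths must be positive")
  spec <- list(
    image_size = as.integer(image_size),
    opening_azimuths = as.numeric(opening_azimuths),
    opening_widths = rep_len(as.numeric(opening_widths), length(opening_azimuths)),
    wall_luminance = wall_luminance,
    floor_luminance = floor_luminance,
    texture_frequency = texture_frequency,
    door_luminance = door_luminance,
    path_contrast = path_contrast,
    horizon_frac = horizon_frac,
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  spec
}

#' Mirror a scene specification left--right
#'
#' @param spec a [scene_spec()].
#' @return The specification with azimuths reflected about 90 degrees.
#' @export
mirror_spec <- function(spec) {
  spec$opening_azimuths <- 180 - spec$opening_azimuths
  spec
}

# Door rectangle column extents on the junction row for each opening.
door_columns <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cx <- floor(w / 2) + 1
  rj <- round(h * spec$horizon_frac)
  dy <- h - rj
  edges <- function(theta) dy * cospi(theta / 180) / sinpi(theta / 180)
  left <- round(cx + pmin(edges(spec$opening_azimuths - spec$opening_widths / 2),
                          edges(spec$opening_azimuths + spec$opening_widths / 2)))
  right <- round(cx + pmax(edges(spec$opening_azimuths - spec$opening_widths / 2),
                           edges(spec$opening_azimuths + spec$opening_widths / 2)))
  data.frame(azimuth = spec$opening_azimuths,
             left = pmax(1L, left), right = pmin(w, right))
}

#' Render a parametric indoor scene
#'
#' Deterministically renders the scene described by a [scene_spec()] as a
#' grayscale intensity matrix in \[0, 1\] (rows top to bottom). The rendered
#' scene carries its ground-truth opening azimuths as an attribute.
#'
#' @param spec a [scene_spec()].
#' @return A `scene_image`: numeric matrix with attributes `azimuths`,
#'   `origin` (bottom-center pixel) and `junction_row`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cx <- floor(w / 2) + 1
  rj <- round(h * spec$horizon_frac)
  doors <- door_columns(spec)
  if (nrow(doors) > 1) {
    o <- order(doors$left)
    d <- doors[o, ]
    overlap <- which(d$left[-1] <= d$right[-nrow(d)])
    abort_if(length(overlap) > 0,
             "openings overlap after rendering: azimuths ",
             paste(sprintf("%.1f/%.1f", d$azimuth[overlap], d$azimuth[overlap + 1]),
                   collapse = ", "), " degrees")
  }

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  f <- spec$texture_frequency
  # Texture is even in (col - cx) so mirrored specs render to mirrored images.
  texture <- 0.05 * cos(2 * pi * f * (cols - cx)) * cos(2 * pi * f * rows)

  # Base luminance map first (wall, floor, doors), then texture on top, so
  # doors at wall luminance are genuinely invisible.
  img <- matrix(spec$wall_luminance, h, w)
  img[rows > rj] <- spec$floor_luminance
  door_top <- max(1, rj - round(0.28 * h))
  for (i in seq_len(nrow(doors))) {
    img[door_top:(rj - 1), doors$left[i]:doors$right[i]] <- spec$door_luminance
  }
  img <- img + texture
  # Floor--wall junction: a dark 2-px band.
  img[rj:min(h, rj + 1), ] <- 0.05

  # Floor path wedges from the origin toward each door center.
  if (spec$path_contrast != 0) {
    bw <- max(1, round(0.02 * w))
    for (i in seq_len(nrow(doors))) {
      target <- (doors$left[i] + doors$right[i]) / 2
      for (r in (rj + 2):h) {
        frac <- (h - r) / (h - rj)
        cc <- cx + frac * (target - cx)
        lo <- max(1, round(cc - bw)); hi <- min(w, round(cc + bw))
        img[r, lo:hi] <- img[r, lo:hi] + spec$path_contrast
      }
    }
  }

  img <- pmin(pmax(img, 0), 1)   # scalar-first pmax would drop dim()
  structure(img,
            azimuths = spec$opening_azimuths,
            origin = c(row = h, col = cx),
            junction_row = rj,
            class = c("scene_image", class(img)))
}

#' Simulate rater navigation-path heat maps
#'
#' Emulates a norming task in which raters trace, with a mouse, the walking
#' path they would take through a scene starting from the bottom center.
#' Each rater is assigned one ground-truth azimuth (round-robin over
#' `truth_azimuths`), perturbs it with Gaussian angular noise, and traces a
#' straight ray from the origin which is rasterized with anti-aliased
#' bilinear weights and normalized to unit mass. The superposed map is
#' optionally blurred with a small mass-conserving Gaussian (reflected at the
#' image border) to mimic mouse-trajectory spread.
#'
#' @param truth_azimuths ground-truth path azimuths in degrees, within (0, 180).
#' @param n_raters number of simulated raters (>= 1).
#' @param angular_noise_sd Gaussian SD of per-rater angular noise, degrees.
#' @param image_size `c(height, width)` of the heat map.
#' @param seed integer seed.
#' @param blur_sd Gaussian blur SD in pixels (0 disables blurring).
#' @return A `path_heat_map`: nonnegative matrix with attribute `origin`
#'   (`c(row = height, col = floor(width / 2) + 1)`); its total mass equals
#'   `n_raters` (one unit of mass per rater path).
#' @export
simulate_rater_paths <- function(truth_azimuths, n_raters = 20,
                                 angular_noise_sd = 5,
                                 image_size = c(227, 227),
                                 seed = 1L, blur_sd = 2) {
  abort_if(length(truth_azimuths) < 1, "truth_azimuths must be non-empty")
  abort_if(n_raters < 1, "n_raters must be >= 1")
  abort_if(any(truth_azimuths <= 0 | truth_azimuths >= 180),
           "azimuths must lie strictly within (0, 180) degrees")
  h <- image_size[1]; w <- image_size[2]
  cx <- floor(w / 2) + 1
  heat <- matrix(0, h, w)
  withr::with_seed(seed, {
    for (i in seq_len(n_raters)) {
      base <- truth_azimuths[(i - 1) %% length(truth_azimuths) + 1]
      theta <- base + if (angular_noise_sd > 0) rnorm(1, 0, angular_noise_sd) else 0
      theta <- min(179.5, max(0.5, theta))
      heat <- heat + rasterize_ray(theta, h, w, cx)
    }
  })
  if (blur_sd > 0) heat <- gaussian_blur_conserve(heat, blur_sd)
  structure(heat, origin = c(row = h, col = cx),
            class = c("path_heat_map", class(heat)))
}

# Anti-aliased rasterization of a ray from (h, cx) at `theta` degrees
# (0 = rightward, 90 = up), normalized to unit total mass.
rasterize_ray <- function(theta, h, w, cx) {
  dx <- cospi(theta / 180)
  dy <- sinpi(theta / 180)
  step <- 0.25
  # Path length until the ray leaves the image.
  tmax_row <- if (dy > 0) (h - 1) / dy else Inf
  tmax_col <- if (dx > 0) (w - cx) / dx else if (dx < 0) (1 - cx) / dx else Inf
  tt <- seq(0, min(tmax_row, tmax_col), by = step)
  rr <- h - tt * dy
  cc <- cx + tt * dx
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  m <- matrix(0, h, w)
  add <- function(r, c, wgt) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w & wgt > 0
    if (any(ok)) {
      idx <- cbind(r[ok], c[ok])
      agg <- rowsum(wgt[ok], group = (idx[, 2] - 1) * h + idx[, 1])
      lin <- as.integer(rownames(agg))
      m[lin] <<- m[lin] + agg[, 1]
    }
  }
  add(r0, c0, (1 - fr) * (1 - fc))
  add(r0 + 1, c0, fr * (1 - fc))
  add(r0, c0 + 1, (1 - fr) * fc)
  add(r0 + 1, c0 + 1, fr * fc)
  m / sum(m)
}

# Separable Gaussian blur that conserves total mass exactly by reflecting
# out-of-range mass back across the image border.
gaussian_blur_conserve <- function(x, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
    out <- matrix(0, n + 2 * half, ncol(m))
    for (j in seq_along(k)) {
      shift <- j - half - 1
      src <- seq_len(n) + half
      out[src + shift, ] <- out[src + shift, ] + k[j] * pad[src, ]
    }
    # Fold reflected margins back in.
    core <- out[(half + 1):(half + n), , drop = FALSE]
    top <- out[seq_len(half), , drop = FALSE]
    bot <- out[(half + n + 1):(2 * half + n), , drop = FALSE]
    core[seq_len(half), ] <- core[seq_len(half), ] + top[half:1, , drop = FALSE]
    core[(n - half + 1):n, ] <- core[(n - half + 1):n, ] + bot[half:1, , drop = FALSE]
    core
  }
  t(blur1(t(blur1(x))))
}

#' Write a grayscale image to PNG
#'
#' @param image numeric matrix (or HxWx3 array) with values in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Read a PNG image as a grayscale matrix
#'
#' RGB and RGBA images are converted with the standard luma weights
#' (0.299, 0.587, 0.114).
#'
#' @param path PNG file path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  to_grayscale(x)
}
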