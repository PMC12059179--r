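# Shape analysis of negative-stain 2D class averages: measure long/short
# outer diameters of the ring by second image moments and classify the ring
# conformation (oval, ATP-free/ADP-bound vs square, ATP-bound) by the
# diameter ratio against the 1.115 threshold.

#' Parameters for the synthetic elliptical-ring class image
#'
#' Emulates a single negative-stain 2D class average of an RCK gating ring:
#' a bright elliptical annulus on a dark background. Ground-truth axes are
#' recorded in the returned image metadata.
#'
#' @param long_axis,short_axis outer diameters in nm
#'   (`long_axis >= short_axis > 0`).
#' @param pixel_size nm per pixel.
#' @param image_size image side length in pixels.
#' @param ring_thickness nm; annulus thickness (outer minus inner radius).
#' @param angle rotation of the long axis in degrees (counter-clockwise).
#' @param noise_sd additive Gaussian noise sd (intensity units; image is 0-1).
#' @param seed RNG seed for the noise.
#' @return List of class `class_image_params`.
#' @export
class_image_params <- function(long_axis = 7.8, short_axis = 6.3,
                               pixel_size = 0.05, image_size = 220,
                               ring_thickness = 1.2, angle = 0,
                               noise_sd = 0, seed = 1) {
  if (short_axis <= 0 || long_axis < short_axis)
    stop_invalid("need long_axis >= short_axis > 0")
  if (pixel_size <= 0) stop_invalid("pixel_size must be positive")
  if (long_axis / pixel_size >= image_size - 2)
    stop_invalid("ellipse exceeds image bounds; enlarge image_size")
  structure(list(long_axis = long_axis, short_axis = short_axis,
                 pixel_size = pixel_size, image_size = as.integer(image_size),
                 ring_thickness = ring_thickness, angle = angle,
                 noise_sd = noise_sd, seed = seed),
            class = "class_image_params")
}

#' Generate a synthetic elliptical-ring class image
#'
#' Renders an anti-aliased elliptical annulus (4x supersampling) with
#' optional rotation and additive Gaussian noise.
#'
#' @param params a [class_image_params()].
#' @return List of class `class_image` with `pixels` (matrix in `[0, 1]`
#'   before noise), `pixel_size` (nm/px) and `truth` (ground-truth axes and
#'   angle).
#' @export
generate_class_image <- function(params) {
  if (!inherits(params, "class_image_params"))
    params <- do.call(class_image_params, params)
  p <- params
  n <- p$image_size
  ss <- 4L  # supersampling factor
  px <- p$pixel_size / ss
  ctr <- (n * ss + 1) / 2
  ij <- expand.grid(row = seq_len(n * ss), col = seq_len(n * ss))
  x <- (ij$col - ctr) * px
  y <- (ij$row - ctr) * px
  th <- p$angle * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  a_out <- p$long_axis / 2; b_out <- p$short_axis / 2
  a_in <- max(a_out - p$ring_thickness, 0.05)
  b_in <- max(b_out - p$ring_thickness, 0.05)
  inside_out <- (u / a_out)^2 + (v / b_out)^2 <= 1
  inside_in <- (u / a_in)^2 + (v / b_in)^2 <= 1
  ring <- inside_out & !inside_in
  hi <- matrix(as.numeric(ring), n * ss, n * ss)
  # box-average the supersampled image down to n x n
  m <- matrix(0, n, n)
  for (a in seq_len(ss)) for (b in seq_len(ss))
    m <- m + hi[seq(a, n * ss, by = ss), seq(b, n * ss, by = ss)]
  m <- m / ss^2
  if (p$noise_sd > 0)
    m <- with_local_seed(p$seed,
                         m + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n))
  structure(list(pixels = m, pixel_size = p$pixel_size,
                 truth = list(long_axis = p$long_axis,
                              short_axis = p$short_axis, angle = p$angle)),
            class = "class_image")
}

#' Measure the long and short outer diameters of a class average
#'
#' Smooths the image, binarizes it with Otsu's global threshold, fills the
#' ring interior, keeps the largest connected component, and reports the
#' outer diameters of the second-moment equivalent ellipse (4 x sqrt of the
#' covariance eigenvalues of the filled object's pixel coordinates), scaled
#' to nm.
#'
#' @param image a `class_image` (from [generate_class_image()] or
#'   [read_class_image()]), or a numeric pixel matrix.
#' @param pixel_size nm per pixel; required when `image` is a bare matrix.
#' @param smooth_sigma Gaussian pre-smoothing sd in pixels.
#' @return List with `long_axis`, `short_axis` (nm), `angle` (degrees) and
#'   `ratio` (long/short).
#' @export
measure_diameters <- function(image, pixel_size = NULL, smooth_sigma = 2) {
  if (inherits(image, "class_image")) {
    pixel_size <- image$pixel_size
    m <- image$pixels
  } else m <- as.matrix(image)
  if (is.null(pixel_size) || pixel_size <= 0)
    stop_invalid("pixel_size must be supplied and positive")
  img <- EBImage::Image(m)
  if (smooth_sigma > 0) img <- EBImage::gblur(img, sigma = smooth_sigma)
  # Otsu needs [0,1]; rescale defensively
  dat <- EBImage::imageData(img)
  rng <- range(dat)
  if (diff(rng) == 0) stop_invalid("image has no foreground (flat intensity)")
  img01 <- EBImage::Image((dat - rng[1]) / diff(rng))
  thr <- EBImage::otsu(img01)
  mask <- img01 > thr
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(sizes) == 0L || max(sizes) == 0L)
    stop_invalid("image has no foreground object after binarization")
  if (sum(sizes > 0.25 * max(sizes)) > 1L)
    warning("multiple large components; keeping the largest")
  keep <- which.max(sizes)
  sel <- which(EBImage::imageData(lab) == keep, arr.ind = TRUE)
  # second-moment equivalent ellipse: full axes = 4 * sqrt(eigenvalues)
  cov <- stats::cov(sel) * (nrow(sel) - 1) / nrow(sel)
  ev <- eigen(cov, symmetric = TRUE)
  ax <- 4 * sqrt(pmax(ev$values, 0)) * pixel_size
  vec <- ev$vectors[, 1]
  list(long_axis = ax[1], short_axis = ax[2],
       angle = (atan2(vec[2], vec[1]) * 180 / pi) %% 180,
       ratio = ax[1] / ax[2])
}

#' Classify a ring conformation from its diameter ratio
#'
#' Ratio = long/short. Ratios below the threshold are called `"square"`
#' (the ATP-bound ring conformation), ratios at or above it `"oval"` (the
#' ADP-bound conformation). Equality is assigned to oval (closed upper
#' set); the published rule states only the strict inequalities.
#'
#' @param long_axis,short_axis diameters (same units, > 0).
#' @param threshold dimensionless ratio threshold (default 1.115).
#' @return List of class `shape_call` with `long_axis`, `short_axis`,
#'   `ratio`, `label`.
#' @export
#' @examples
#' classify_shape(7.8, 6.3)$label  # "oval"
classify_shape <- function(long_axis, short_axis, threshold = 1.115) {
  if (short_axis <= 0 || long_axis <= 0) stop_invalid("axes must be positive")
  if (long_axis < short_axis) { tmp <- long_axis; long_axis <- short_axis
                                short_axis <- tmp }
  ratio <- long_axis / short_axis
  structure(list(long_axis = long_axis, short_axis = short_axis,
                 ratio = ratio,
                 label = if (ratio < threshold) "square" else "oval"),
            class = "shape_call")
}

#' Particle-weighted oval/square fractions over a set of class calls
#'
#' @param calls list of [classify_shape()] results, or a data.frame with a
#'   `label` column.
#' @param n_particles numeric vector of particles contributing to each
#'   class; when missing or all zero, unweighted class fractions are
#'   returned with a warning.
#' @return List with `fraction_oval`, `fraction_square` (summing to 1).
#' @export
shape_fractions <- function(calls, n_particles = NULL) {
  labels <- if (is.data.frame(calls)) calls$label
            else vapply(calls, function(c) c$label, character(1))
  if (length(labels) == 0L) stop_invalid("need at least one shape call")
  if (is.null(n_particles)) n_particles <- rep(1, length(labels))
  if (sum(n_particles) == 0) {
    warning("zero total particles; returning unweighted class fractions")
    n_particles <- rep(1, length(labels))
  }
  w <- n_particles / sum(n_particles)
  fo <- sum(w[labels == "oval"])
  list(fraction_oval = fo, fraction_square = 1 - fo)
}
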