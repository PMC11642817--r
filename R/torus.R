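#' Minimum-image distance on the torus
#'
#' Euclidean distance between points of the `L` x `L` torus under the
#' minimum-image convention; the largest attainable separation is
#' `L / sqrt(2)`.
#'
#' @param a,b Numeric length-2 points, or n x 2 matrices of points
#'   (recycled row-wise against each other).
#' @param L Habitat side length.
#' @return Distance(s).
#' @examples
#' torus_distance(c(0, 0), c(9, 0), L = 10)  # wraps to 1
#' @export
torus_distance <- function(a, b, L) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) < n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) < n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  d <- abs(a %% L - b %% L)
  d <- pmin(d, L - d)
  sqrt(rowSums(d^2))
}

# Per-axis wrapped-normal density on [0, L): sum of Gaussian images at
# offsets j*L with |j| <= n_images. Truncation at ceil(6*w/L) + 1 images
# keeps the error below 1e-12 (images beyond 6 sd are negligible).
wrapped_norm_1d <- function(dx, w, L) {
  n_img <- ceiling(6 * w / L) + 1L
  j <- seq.int(-n_img, n_img)
  dens <- numeric(length(dx))
  for (jj in j) dens <- dens + stats::dnorm(dx + jj * L, sd = w)
  dens
}

#' Sampling-kernel density on the torus
#'
#' Density per unit area of the sampling kernel at point(s) `p`, normalized
#' so that the integral over the habitat is 1. The Gaussian kernel is the
#' wrapped normal (product of per-axis wrapped normals); the uniform kernel
#' is `1 / L^2` everywhere.
#'
#' @param kernel A [sampling_kernel()] object.
#' @param p Numeric length-2 point or n x 2 matrix of points.
#' @param L Habitat side length.
#' @return Density value(s) per unit area.
#' @export
kernel_density <- function(kernel, p, L) {
  stopifnot(inherits(kernel, "sampling_kernel"), is.numeric(L), L > 0)
  p <- matrix(as.numeric(p), ncol = 2)
  if (kernel$kind == "uniform")
    return(rep(1 / L^2, nrow(p)))
  dx <- (p[, 1] - kernel$center[1]) %% L
  dy <- (p[, 2] - kernel$center[2]) %% L
  # map to [-L/2, L/2): the image sum is symmetric so any representative works
  dx <- dx - L * (dx >= L / 2)
  dy <- dy - L * (dy >= L / 2)
  wrapped_norm_1d(dx, kernel$width, L) * wrapped_norm_1d(dy, kernel$width, L)
}

#' Brownian dispersal step with periodic wrapping
#'
#' Advance point(s) by isotropic Brownian motion for `dt` generations and
#' wrap modulo `L`. Each axis receives an independent Gaussian displacement
#' of variance `(sigma^2 / 2) * dt`, so the RMS two-dimensional displacement
#' over one generation is exactly `sigma` (the model's definition of the
#' dispersal scale; the alternative convention of `sigma` per axis would
#' change `ell_c` by a factor of 2).
#'
#' @param p Numeric length-2 point or n x 2 matrix of points.
#' @param dt Elapsed time in generations (>= 0).
#' @param sigma RMS 2-D dispersal distance per generation.
#' @param L Habitat side length.
#' @return Point(s) of the same shape as `p`, wrapped to `[0, L)`.
#' @export
wrap_brownian_step <- function(p, dt, sigma, L) {
  stopifnot(is.numeric(dt), all(dt >= 0), sigma > 0, L > 0)
  was_vec <- is.null(dim(p))
  p <- matrix(as.numeric(p), ncol = 2)
  if (any(dt > 0)) {
    sd_axis <- sigma * sqrt(dt / 2)
    p[, 1] <- p[, 1] + stats::rnorm(nrow(p), sd = sd_axis)
    p[, 2] <- p[, 2] + stats::rnorm(nrow(p), sd = sd_axis)
  }
  p <- p %% L
  if (was_vec) as.numeric(p) else p
}
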