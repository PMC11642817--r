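#' Population and habitat parameters
#'
#' Bundle the biological and spatial parameters of the model: a population of
#' density `rho` individuals per unit area lives on an `L` x `L` torus;
#' carriers of a deleterious allele disperse with root-mean-squared
#' per-generation displacement `sigma` (in habitat length units), new carriers
#' arise by mutation at rate `mu` per site per generation, and each carrier
#' pays a fitness cost `s` (reproduction rate `1 - s`, death rate 1).
#'
#' @param sigma RMS two-dimensional dispersal distance per generation (> 0).
#' @param rho Population density, individuals per unit area (> 0).
#' @param mu Mutation rate per site per generation (>= 0; zero is allowed
#'   so that mutation-free habitats can be simulated, but the effective-
#'   parameter theory requires `mu > 0`).
#' @param s Heterozygous selection coefficient in (0, 1); larger positive `s`
#'   means stronger negative selection. `s = 0` is rejected because the
#'   characteristic length `sigma^2 / s` is then undefined.
#' @param L Habitat side length (> 0); the habitat is an `L` x `L` torus.
#'
#' @return An object of class `pop_params`: a list with fields `sigma`, `rho`,
#'   `mu`, `s`, `L` and the derived total population size `N = rho * L^2`.
#'
#' @examples
#' pop <- pop_params(sigma = 10, rho = 20, mu = 1e-9, s = 0.01, L = 1000)
#' pop$N  # 2e7
#' @export
pop_params <- function(sigma, rho, mu, s, L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L,
            is.numeric(rho), length(rho) == 1L,
            is.numeric(mu), length(mu) == 1L,
            is.numeric(s), length(s) == 1L,
            is.numeric(L), length(L) == 1L)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!is.finite(rho) || rho <= 0) stop("`rho` must be > 0")
  if (!is.finite(mu) || mu < 0) stop("`mu` must be >= 0")
  if (!is.finite(s) || s <= 0 || s >= 1) stop("`s` must lie in (0, 1)")
  if (!is.finite(L) || L <= 0) stop("`L` must be > 0")
  structure(
    list(sigma = sigma, rho = rho, mu = mu, s = s, L = L, N = rho * L^2),
    class = "pop_params"
  )
}

#' @method print pop_params
#' @export
print.pop_params <- function(x, ...) {
  cat("Population parameters (2-D torus habitat)\n")
  cat(sprintf("  sigma = %g  rho = %g  mu = %g  s = %g  L = %g\n",
              x$sigma, x$rho, x$mu, x$s, x$L))
  cat(sprintf("  N = rho * L^2 = %g   ell_c = sigma/sqrt(2s) = %g\n",
              x$N, x$sigma / sqrt(2 * x$s)))
  invisible(x)
}

#' Spatial sampling kernel
#'
#' Describe the spatial density of sampling probability on the torus: either
#' a wrapped Gaussian of standard deviation `width` centred at `center`
#' (geographically concentrated sampling), or the uniform kernel under which
#' every individual is equally likely to be sampled regardless of position.
#'
#' @param kind `"gaussian"` or `"uniform"`.
#' @param center Numeric length-2 coordinate of the sampling centre
#'   (ignored for the uniform kernel).
#' @param width Standard deviation `w` of the Gaussian kernel, in the same
#'   units as the habitat side `L`; required (> 0) when `kind = "gaussian"`.
#'
#' @return An object of class `sampling_kernel`.
#' @examples
#' sampling_kernel("gaussian", center = c(500, 500), width = 40)
#' sampling_kernel("uniform")
#' @export
sampling_kernel <- function(kind = c("gaussian", "uniform"),
                            center = c(0, 0), width = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(width) || !is.numeric(width) || length(width) != 1L ||
        !is.finite(width) || width <= 0)
      stop("gaussian kernel requires `width` > 0")
  } else {
    width <- NA_real_
  }
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(kind = kind, center = as.numeric(center), width = width),
            class = "sampling_kernel")
}

#' @method print sampling_kernel
#' @export
print.sampling_kernel <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("Sampling kernel: uniform\n")
  } else {
    cat(sprintf("Sampling kernel: gaussian, center = (%g, %g), width w = %g\n",
                x$center[1], x$center[2], x$width))
  }
  invisible(x)
}
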