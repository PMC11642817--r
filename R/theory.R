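#' Characteristic length scale of a deleterious allele
#'
#' An allele under selection `s` persists for about `1/s` generations, during
#' which its carrier lineages diffuse with total RMS displacement `sigma`
#' per generation — `sigma^2/2` of variance per axis and per generation. The
#' typical per-axis spatial extent of the carrier cloud before extinction is
#' therefore `ell_c = sigma / sqrt(2 s)` (so `ell_c^2 = sigma^2 / (2 s)`,
#' and `rho * ell_c^2` is the population-size scale of the carriers'
#' footprint, the same structure as Wright's neighbourhood size
#' `4 pi sigma^2 rho`). The ratio of the sampling-kernel width (itself a
#' per-axis standard deviation) to this scale governs the whole sampling
#' effect; the branching simulator confirms this convention (see the
#' methods vignette).
#'
#' @param sigma RMS dispersal distance per generation (> 0).
#' @param s Selection coefficient in (0, 1).
#' @return The characteristic length `sigma / sqrt(2 s)` (habitat length
#'   units).
#' @examples
#' characteristic_length(10, 0.01)  # 70.7
#' @export
characteristic_length <- function(sigma, s) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be > 0")
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("`s` must lie in (0, 1)")
  sigma / sqrt(2 * s)
}

# Scaled exponential integral e^x * E1(x), stable for all x > 0.
# Direct product below x = 40; modified Lentz continued fraction
#   e^x E1(x) = 1 / (x + 1 - 1^2/(x + 3 - 2^2/(x + 5 - ...)))
# above, where exp(x) would overflow / E1(x) underflow.
expE1 <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  out <- numeric(length(x))
  lo <- x < 40
  if (any(lo)) out[lo] <- exp(x[lo]) * pracma::expint(x[lo])
  if (any(!lo)) {
    out[!lo] <- vapply(x[!lo], function(xx) {
      # modified Lentz on 1/(x+1 - 1^2/(x+3 - 2^2/(x+5 - ...)))
      tiny <- 1e-300
      f <- tiny; C <- tiny; D <- 0
      aj <- 1; bj <- xx + 1
      for (k in 0:300) {
        if (k > 0) { aj <- -k^2; bj <- xx + 2 * k + 1 }
        D <- bj + aj * D; if (D == 0) D <- tiny
        C <- bj + aj / C; if (C == 0) C <- tiny
        D <- 1 / D
        delta <- C * D
        f <- f * delta
        if (abs(delta - 1) < 1e-15) break
      }
      f
    }, numeric(1))
  }
  out
}

#' Sampling effect scalar
#'
#' The dimensionless factor `lambda` by which both effective SFS parameters
#' scale with the breadth of a Gaussian sampling kernel. With
#' `x = (w / ell_c)^2`,
#' \deqn{\lambda = \frac{4\pi}{e^{x} E_1(x)},}
#' where `E1` is the exponential integral. `lambda` increases strictly with
#' `w` at fixed `ell_c`, vanishes as `w -> 0` (point sampling), and satisfies
#' `lambda ~ 4 pi (w/ell_c)^2` as `w/ell_c -> Inf`, so the effective
#' population sampled, `rho * ell_c^2 * lambda`, grows like `4 pi rho w^2`.
#'
#' @param w Gaussian kernel width (> 0), habitat length units.
#' @param ell_c Characteristic length (> 0), same units.
#' @return `lambda` (dimensionless), vectorised over `w`.
#' @examples
#' sampling_effect_scalar(w = 100, ell_c = 100)  # x = 1 -> 21.072
#' @export
sampling_effect_scalar <- function(w, ell_c) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    stop("`w` must be > 0")
  if (!is.numeric(ell_c) || any(!is.finite(ell_c)) || any(ell_c <= 0))
    stop("`ell_c` must be > 0")
  x <- (w / ell_c)^2
  4 * pi / expE1(x)
}

#' Effective SFS parameters
#'
#' Construct an `eff_params` object holding the two parameters of the
#' gamma-distributed weighted allele frequency (and hence of the
#' negative-binomial finite-sample SFS): the effective mutation supply
#' `theta_E` and the effective selection intensity `gamma_E`.
#' Their ratio is always `mu / s`, the mean allele frequency.
#'
#' @param theta_E Effective mutation supply (> 0).
#' @param gamma_E Effective selection intensity (> 0).
#' @param ell_c Characteristic length (optional, for provenance).
#' @param lam Sampling effect scalar (optional, for provenance).
#' @param kind Kernel kind the parameters were derived under (optional).
#' @return An object of class `eff_params`.
#' @export
eff_params <- function(theta_E, gamma_E, ell_c = NA_real_, lam = NA_real_,
                       kind = NA_character_) {
  stopifnot(is.numeric(theta_E), length(theta_E) == 1L, theta_E > 0,
            is.numeric(gamma_E), length(gamma_E) == 1L, gamma_E > 0)
  structure(list(theta_E = theta_E, gamma_E = gamma_E,
                 ell_c = ell_c, lam = lam, kind = kind),
            class = "eff_params")
}

#' @method print eff_params
#' @export
print.eff_params <- function(x, ...) {
  cat(sprintf("Effective SFS parameters%s\n",
              if (is.na(x$kind)) "" else sprintf(" (%s kernel)", x$kind)))
  cat(sprintf("  theta_E = %g   gamma_E = %g   theta_E/gamma_E = %g\n",
              x$theta_E, x$gamma_E, x$theta_E / x$gamma_E))
  if (!is.na(x$lam))
    cat(sprintf("  ell_c = %g   lambda = %g\n", x$ell_c, x$lam))
  invisible(x)
}

#' Effective mutation supply and selection intensity for a sampling design
#'
#' For a Gaussian kernel of width `w` (spatially concentrated sampling,
#' valid for `w << L`):
#' \deqn{\theta_E = \mu\,\rho\,\ell_c^2\,\lambda, \qquad
#'       \gamma_E = s\,\rho\,\ell_c^2\,\lambda,}
#' where `rho * ell_c^2 * lambda` approximates the size of the population
#' effectively being sampled. For the uniform kernel the parameters are the
#' usual population-scaled quantities `theta_E = N mu`, `gamma_E = N s`.
#' In both cases `theta_E / gamma_E = mu / s` exactly.
#'
#' A warning (not an error) is emitted when the Gaussian-regime effective
#' population `rho * ell_c^2 * lambda` exceeds `N`: the kernel width is then
#' not small compared to `L` and the concentrated-sampling formulas leave
#' their validity domain (the true behaviour converges to uniform sampling).
#'
#' @param pop A [pop_params()] object.
#' @param kernel A [sampling_kernel()] object.
#' @return An [eff_params()] object; the effective population sampled is
#'   attached as attribute `"N_eff"`.
#' @examples
#' pop <- pop_params(sigma = 10, rho = 20, mu = 1e-9, s = 0.01, L = 1000)
#' effective_params(pop, sampling_kernel("uniform"))
#' @export
effective_params <- function(pop, kernel) {
  stopifnot(inherits(pop, "pop_params"), inherits(kernel, "sampling_kernel"))
  if (pop$mu <= 0) stop("effective parameters require `mu` > 0")
  ell_c <- characteristic_length(pop$sigma, pop$s)
  if (kernel$kind == "uniform") {
    eff <- eff_params(theta_E = pop$N * pop$mu, gamma_E = pop$N * pop$s,
                      ell_c = ell_c, lam = NA_real_, kind = "uniform")
    attr(eff, "N_eff") <- pop$N
    return(eff)
  }
  lam <- sampling_effect_scalar(kernel$width, ell_c)
  N_eff <- pop$rho * ell_c^2 * lam
  if (N_eff > pop$N)
    warning(sprintf(paste0(
      "effective population sampled (%.4g) exceeds N = %.4g; ",
      "kernel width w = %g is not << L = %g and the concentrated-sampling ",
      "formulas are outside their validity domain (behaviour converges to ",
      "uniform sampling)"), N_eff, pop$N, kernel$width, pop$L))
  eff <- eff_params(theta_E = pop$mu * N_eff, gamma_E = pop$s * N_eff,
                    ell_c = ell_c, lam = lam, kind = "gaussian")
  attr(eff, "N_eff") <- N_eff
  eff
}

#' Finite-sample SFS probability mass function
#'
#' The count `K` of derived alleles at a site in a sample of size `n` follows
#' a negative binomial distribution with `theta_E` "successes" and success
#' probability `gamma_E / (gamma_E + n)` — the Poisson(n x) mixture of the
#' gamma-distributed weighted allele frequency x. The support is not
#' truncated at `k = n`: the Poisson approximation to binomial sampling
#' permits `k > n` with negligible mass for rare alleles.
#'
#' @param eff An [eff_params()] object.
#' @param n Sample size (haploid, >= 1).
#' @param k Allele count(s), non-negative integer(s).
#' @param log If `TRUE` return log probabilities.
#' @return `Pr(K = k)`, vectorised over `k`.
#' @examples
#' e <- eff_params(theta_E = 1, gamma_E = 100)
#' sfs_pmf(e, n = 100, k = 0)  # 0.5: geometric with p = 1/2
#' @export
sfs_pmf <- function(eff, n, k, log = FALSE) {
  stopifnot(inherits(eff, "eff_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(k) || any(k < 0) || any(k != round(k)))
    stop("`k` must be non-negative integer(s)")
  stats::dnbinom(k, size = eff$theta_E,
                 prob = eff$gamma_E / (eff$gamma_E + n), log = log)
}

#' Small-theta approximation to the variant SFS
#'
#' In the limit of small `theta_E` the normalized SFS entry for variant
#' counts `k >= 1` reduces to
#' \deqn{\xi_k(n) = \frac{\theta_E}{k}\left(\frac{n}{\gamma_E+n}\right)^k,}
#' the familiar `theta/k` mutation-drift profile damped geometrically by
#' selection through `gamma_E`.
#'
#' @inheritParams sfs_pmf
#' @param k Allele count(s), `k >= 1` (the expansion is defined for variant
#'   counts only; `k = 0` is a domain error).
#' @return Approximate `xi_k(n)`, vectorised over `k`.
#' @export
sfs_small_theta <- function(eff, n, k) {
  stopifnot(inherits(eff, "eff_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(k) || any(k < 1) || any(k != round(k)))
    stop("`k` must be integer(s) >= 1 (small-theta SFS is for variant counts)")
  (eff$theta_E / k) * (n / (eff$gamma_E + n))^k
}

#' Expected SFS summary statistics
#'
#' Closed-form expectations of the summary statistics of an observed sample
#' SFS under the negative-binomial model. The expected allele frequency over
#' all sites equals `mu / s` exactly, independent of the sampling kernel,
#' width and sample size — the discovery and dilution effects cancel. The
#' expected heterozygosity and cumulative MAF are reported with the
#' rare-allele approximation (proportional to the mean frequency):
#' `het = 2 mu/s` and `cmaf = M mu/s`; the exact gamma moment
#' `E[2x(1-x)] = 2(theta/gamma - theta(theta+1)/gamma^2)` is attached as
#' `het_exact`.
#'
#' @param eff An [eff_params()] object.
#' @param pop The [pop_params()] the effective parameters were derived from
#'   (used for the `mu/s` identity and consistency checking).
#' @param n Sample size (haploid).
#' @param M Number of surveyed sites (monomorphic included); used for `cmaf`.
#' @return A list of class `sfs_expectations` with fields `p_variant`,
#'   `p_singleton`, `mean_freq_variant`, `mean_freq_all`, `het`,
#'   `het_exact`, `cmaf`.
#' @export
expected_summary_stats <- function(eff, pop, n, M = 1) {
  stopifnot(inherits(eff, "eff_params"), inherits(pop, "pop_params"))
  ratio <- eff$theta_E / eff$gamma_E
  if (abs(ratio - pop$mu / pop$s) > 1e-8 * (pop$mu / pop$s))
    stop("`eff` inconsistent with `pop`: theta_E/gamma_E != mu/s")
  p0 <- sfs_pmf(eff, n, 0L)
  p_variant <- 1 - p0
  p_singleton <- sfs_pmf(eff, n, 1L)
  mean_freq_all <- pop$mu / pop$s  # = E[K]/n = theta_E/gamma_E exactly
  structure(list(
    p_variant = p_variant,
    p_singleton = p_singleton,
    mean_freq_variant = mean_freq_all / p_variant,
    mean_freq_all = mean_freq_all,
    het = 2 * mean_freq_all,
    het_exact = 2 * (ratio - eff$theta_E * (eff$theta_E + 1) / eff$gamma_E^2),
    cmaf = M * mean_freq_all
  ), class = "sfs_expectations")
}

#' @method print sfs_expectations
#' @export
print.sfs_expectations <- function(x, ...) {
  cat("Expected SFS summary statistics\n")
  for (f in c("p_variant", "p_singleton", "mean_freq_variant",
              "mean_freq_all", "het", "het_exact", "cmaf"))
    cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' Equilibrium density of the weighted population allele frequency
#'
#' The kernel-weighted allele frequency of a site at equilibrium is
#' approximately gamma distributed with shape `theta_E` and rate `gamma_E`:
#' power-law behaviour at low frequency from mutation-drift balance, an
#' exponential tail from selection. Mean `theta_E/gamma_E = mu/s`,
#' variance `theta_E/gamma_E^2`. (The `x -> 1` tail of the full panmictic
#' density is outside the rare-allele regime and is not modelled.)
#'
#' @param eff An [eff_params()] object.
#' @param x Weighted allele frequency, `x > 0`.
#' @param log If `TRUE` return the log density.
#' @return Density value(s) at `x`.
#' @export
population_afd_density <- function(eff, x, log = FALSE) {
  stopifnot(inherits(eff, "eff_params"))
  if (!is.numeric(x) || any(x <= 0))
    stop("`x` must be > 0")
  stats::dgamma(x, shape = eff$theta_E, rate = eff$gamma_E, log = log)
}
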