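# Independent numerical oracles used across tests.

# Exponential integral E1 by direct quadrature of its defining integral,
# independent of the special-function route used by the package.
e1_quadrature <- function(x) {
  vapply(x, function(xx)
    stats::integrate(function(t) exp(-xx * t) / t, 1, Inf,
                     rel.tol = 1e-12)$value, numeric(1))
}

# Gamma-Poisson mixture pmf by adaptive quadrature:
#   Pr(K = k) = int Pois(k; n*x) Gamma(x; shape = theta, rate = gamma) dx.
# The integrand has an integrable x^(theta-1) singularity at 0 when
# theta < 1 and k = 0; substituting u = x^theta on (0, 1) removes it.
mixture_pmf_quadrature <- function(k, theta, gamma, n) {
  vapply(k, function(kk) {
    f <- function(x) stats::dpois(kk, n * x) * stats::dgamma(x, shape = theta,
                                                             rate = gamma)
    if (kk == 0 && theta < 1) {
      # u = x^theta on x in (0,1): integrand becomes bounded
      g <- function(u) {
        x <- u^(1 / theta)
        stats::dpois(0, n * x) * gamma^theta * exp(-gamma * x) /
          (theta * base::gamma(theta))
      }
      i1 <- stats::integrate(g, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
      i2 <- stats::integrate(f, 1, Inf, rel.tol = 1e-12,
                             abs.tol = 1e-14)$value
      i1 + i2
    } else {
      # integrand is proportional to a Gamma(theta + k, gamma + n) density
      upper <- stats::qgamma(1 - 1e-14, shape = theta + kk, rate = gamma + n)
      stats::integrate(f, 0, upper, rel.tol = 1e-12, abs.tol = 1e-14)$value
    }
  }, numeric(1))
}

# Reference population shared by several tests: a human-scale habitat with
# realistic per-site mutation rate and moderate selection.
ref_pop <- function() pop_params(sigma = 10, rho = 20, mu = 1e-9,
                                 s = 0.01, L = 1000)
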