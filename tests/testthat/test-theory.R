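test_that("characteristic length is the diffusive spread over the allele lifetime", {
  # sigma/sqrt(2s): per-axis variance sigma^2/2 per generation integrated
  # over the ~1/s-generation lifetime; squared it is sigma^2/(2s)
  expect_equal(characteristic_length(10, 0.01), 10 / sqrt(0.02))
  expect_equal(characteristic_length(1, 0.5), 1)
  expect_equal(characteristic_length(2, 0.1), 2 / sqrt(0.2))
  expect_equal(characteristic_length(10, 0.01)^2, 10^2 / (2 * 0.01))
  expect_error(characteristic_length(-1, 0.1), "sigma")
  expect_error(characteristic_length(1, 0), "s")
  expect_error(characteristic_length(1, 1), "s")
})

test_that("sampling effect scalar matches the quadrature oracle", {
  # frozen values computed from lambda = 4*pi / (e^x E1(x)) with E1 by
  # direct quadrature of int_1^Inf e^(-x t)/t dt
  expect_equal(sampling_effect_scalar(1, 1), 21.0722, tolerance = 1e-4)
  expect_equal(sampling_effect_scalar(0.1, 1), 3.0811, tolerance = 1e-4)
  for (x in c(1e-4, 0.01, 0.3, 1, 7, 35)) {
    lam_oracle <- 4 * pi / (exp(x) * e1_quadrature(x))
    expect_equal(sampling_effect_scalar(sqrt(x), 1), lam_oracle,
                 tolerance = 1e-9)
  }
  expect_error(sampling_effect_scalar(-1, 1))
  expect_error(sampling_effect_scalar(1, 0))
})

test_that("lambda is strictly increasing and reaches its quadratic asymptote", {
  wr <- 10^seq(-3, 3, length.out = 121)  # w / ell_c
  lam <- sampling_effect_scalar(wr, 1)
  expect_true(all(is.finite(lam)))
  expect_true(all(diff(lam) > 0))
  big <- wr >= 30
  expect_true(all(abs(lam[big] / (4 * pi * wr[big]^2) - 1) < 0.01))
  # no overflow far beyond the asymptote
  expect_true(is.finite(sampling_effect_scalar(1e3, 1)))
})

test_that("effective parameters obey the uniform limit and the mu/s identity", {
  pop <- ref_pop()  # N = 2e7
  eu <- effective_params(pop, sampling_kernel("uniform"))
  expect_identical(eu$theta_E, pop$N * pop$mu)  # 0.02
  expect_identical(eu$gamma_E, pop$N * pop$s)   # 2e5
  # gaussian: composition with the sampling-effect oracle at w = ell_c
  ell <- characteristic_length(pop$sigma, pop$s)  # 70.71
  ker <- sampling_kernel("gaussian", c(500, 500), width = ell)
  eg <- effective_params(pop, ker)
  lam <- 4 * pi / (exp(1) * e1_quadrature(1))
  expect_equal(eg$theta_E, 1e-9 * 20 * ell^2 * lam, tolerance = 1e-9)
  expect_equal(eg$gamma_E, 0.01 * 20 * ell^2 * lam, tolerance = 1e-9)
  for (w in c(5, 30, 100, 250)) {
    e <- effective_params(pop, sampling_kernel("gaussian", c(0, 0), w))
    expect_equal(e$theta_E / e$gamma_E, pop$mu / pop$s, tolerance = 1e-15)
  }
})

test_that("a warning fires when the effective population exceeds N", {
  pop <- pop_params(sigma = 10, rho = 20, mu = 1e-9, s = 0.01, L = 100)
  expect_warning(effective_params(pop, sampling_kernel("gaussian", c(0, 0), 90)),
                 "exceeds N")
  big <- ref_pop()
  expect_silent(effective_params(big, sampling_kernel("gaussian", c(0, 0), 40)))
})

test_that("negative-binomial SFS pmf equals the gamma-Poisson mixture", {
  # geometric special case theta_E = 1, gamma_E = n
  e <- eff_params(theta_E = 1, gamma_E = 50)
  expect_equal(sfs_pmf(e, 50, 0L), 0.5)
  expect_equal(sfs_pmf(e, 50, 1L), 0.25)
  # quadrature oracle across regimes, including the headline parameters
  grid <- expand.grid(theta = c(1e-3, 0.02, 1), gamma = c(1e2, 2e5),
                      n = c(1e3, 1e4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    eff <- eff_params(g$theta, g$gamma)
    k <- 0:50
    expect_lt(max(abs(sfs_pmf(eff, g$n, k) -
                        mixture_pmf_quadrature(k, g$theta, g$gamma, g$n))),
              1e-10)
  }
  # normalization over the untruncated support
  eff <- eff_params(0.02, 2e5)
  expect_equal(sum(sfs_pmf(eff, 1e4, 0:2000)), 1, tolerance = 1e-12)
  expect_error(sfs_pmf(eff, 0, 1))
  expect_error(sfs_pmf(eff, 10, -1))
})

test_that("small-theta expansion matches the pmf within its error bound", {
  e <- eff_params(theta_E = 1, gamma_E = 1000)
  n <- 100
  expect_equal(sfs_small_theta(e, n, 1L), e$theta_E * n / (e$gamma_E + n))
  expect_error(sfs_small_theta(e, n, 0L), "k")
  # exact first-order error: pmf/xi = 1 + theta*(H_{k-1} + ln p) + O(theta^2)
  # with p = gamma/(gamma+n); the two terms cancel when n >> gamma
  for (theta in c(1e-3, 1e-2)) {
    for (gamma in c(50, 1e4, 2e5)) {
      for (n in c(1e3, 1e4)) {
        eff <- eff_params(theta, gamma)
        k <- 1:20
        rel <- abs(sfs_small_theta(eff, n, k) / sfs_pmf(eff, n, k) - 1)
        H <- c(0, cumsum(1 / seq_len(19)))
        bound <- theta * abs(H + log(gamma / (gamma + n))) + 25 * theta^2
        expect_true(all(rel <= bound))
      }
    }
  }
  # where harmonic and log terms balance (n ~ 5 gamma) the error stays
  # within 2 * theta over k <= 20
  eff <- eff_params(0.01, 100)
  rel <- abs(sfs_small_theta(eff, 500, 1:20) / sfs_pmf(eff, 500, 1:20) - 1)
  expect_lt(max(rel), 2 * 0.01)
  # strong-selection limit: entries vanish
  eff <- eff_params(1e-3, 1e12)
  expect_lt(max(sfs_small_theta(eff, 1e4, 1:10)), 1e-10)
})

test_that("expected summary statistics: identities and cross-checks", {
  pop <- ref_pop()
  eu <- effective_params(pop, sampling_kernel("uniform"))
  st <- expected_summary_stats(eu, pop, n = 1e4, M = 1e6)
  expect_identical(st$mean_freq_all, pop$mu / pop$s)
  expect_equal(st$p_variant,
               1 - (eu$gamma_E / (eu$gamma_E + 1e4))^eu$theta_E)
  # cross-check p_variant by summing the pmf over k >= 1
  expect_equal(st$p_variant, sum(sfs_pmf(eu, 1e4, 1:5000)),
               tolerance = 1e-10)
  expect_equal(st$p_singleton, sfs_pmf(eu, 1e4, 1L))
  expect_lte(st$p_singleton, st$p_variant)
  expect_gte(st$mean_freq_variant, st$mean_freq_all)
  expect_equal(st$cmaf, 1e6 * pop$mu / pop$s)
  expect_equal(st$het, 2 * pop$mu / pop$s)
  expect_lt(st$het_exact, st$het)  # exact moment subtracts the x^2 term
})

test_that("discovery, dilution, and the mu/s invariance across widths", {
  pop <- ref_pop()
  widths <- exp(seq(log(5), log(250), length.out = 50))
  effs <- lapply(widths, function(w)
    effective_params(pop, sampling_kernel("gaussian", c(0, 0), w)))
  stats <- lapply(effs, expected_summary_stats, pop = pop, n = 1e4)
  p_var <- vapply(stats, `[[`, numeric(1), "p_variant")
  mf_var <- vapply(stats, `[[`, numeric(1), "mean_freq_variant")
  mf_all <- vapply(stats, `[[`, numeric(1), "mean_freq_all")
  expect_true(all(diff(p_var) > 0))         # discovery
  expect_true(all(diff(mf_var) < 0))        # dilution
  expect_identical(unique(mf_all), pop$mu / pop$s)  # exact invariance
})

test_that("uniform-kernel SFS matches the panmictic gamma model at small theta", {
  # under uniform sampling the spectrum entries reduce to the small-theta
  # expansion of the panmictic two-parameter model with theta = N*mu and
  # gamma = N*s: xi_k = (theta/k) * (n/(n+gamma))^k
  pop <- ref_pop()
  eu <- effective_params(pop, sampling_kernel("uniform"))
  n <- 1e4
  k <- 1:30
  panmictic <- (pop$N * pop$mu / k) * (n / (n + pop$N * pop$s))^k
  expect_equal(sfs_small_theta(eu, n, k), panmictic, tolerance = 1e-12)
  expect_equal(sfs_pmf(eu, n, k), panmictic, tolerance = 2 * eu$theta_E)
})

test_that("population allele-frequency density is the matching gamma", {
  eff <- eff_params(0.5, 200)
  x <- c(1e-5, 1e-3, 0.01)
  expect_equal(population_afd_density(eff, x),
               dgamma(x, shape = 0.5, rate = 200))
  # theta_E = 1 reduces to an exponential
  e1 <- eff_params(1, 300)
  expect_equal(population_afd_density(e1, x), dexp(x, rate = 300))
  # mean of the density is mu/s = theta/gamma
  m <- integrate(function(x) x * population_afd_density(eff, x), 0, Inf)$value
  expect_equal(m, eff$theta_E / eff$gamma_E, tolerance = 1e-5)
  expect_error(population_afd_density(eff, 0))
})
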