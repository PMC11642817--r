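tiny_cohort <- function(n = 200, L = 10, seed = 1, n_sites = 5) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, L), runif(n, 0, L))
  g <- Matrix::sparseMatrix(i = sample.int(n_sites, 20, replace = TRUE),
                            j = sample.int(n, 20),
                            x = 1, dims = c(n_sites, n))
  cohort(ids = sprintf("i%03d", seq_len(n)), coords = coords, genotypes = g)
}

test_that("KDE density is near-constant on a uniform grid away from edges", {
  g <- seq(0.01, 0.99, length.out = 50)
  coords <- as.matrix(expand.grid(g, g))
  dens <- estimate_sampling_density(coords, method = "kde")
  expect_true(all(dens > 0))
  bw <- MASS::bandwidth.nrd(coords[, 1])
  interior <- coords[, 1] > bw & coords[, 1] < 1 - bw &
    coords[, 2] > bw & coords[, 2] < 1 - bw
  cv <- sd(dens[interior]) / mean(dens[interior])
  expect_lt(cv, 0.05)
  expect_identical(attr(dens, "method"), "kde")
})

test_that("density estimates resolve unequal cluster sizes", {
  set.seed(21)
  big <- cbind(rnorm(2000, 0, 0.5), rnorm(2000, 0, 0.5))
  small <- cbind(rnorm(1000, 10, 0.5), rnorm(1000, 0, 0.5))
  coords <- rbind(big, small)
  dens <- estimate_sampling_density(coords, method = "hist", gridsize = 40L)
  ratio <- mean(dens[1:2000]) / mean(dens[2001:3000])
  expect_equal(ratio, 2, tolerance = 0.2)
  expect_error(estimate_sampling_density(matrix(1, 5, 2)), "degenerate")
  expect_error(estimate_sampling_density(coords[1, , drop = FALSE]), "2")
})

test_that("uniform SIR target reduces to a seeded simple random sample", {
  cht <- tiny_cohort()
  spec <- resample_spec(size = 50, replicates = 3, seed = 42,
                        kind = "uniform")
  idx <- sir_resample(cht, spec)
  expect_length(idx, 3)
  expect_true(all(vapply(idx, length, integer(1)) == 50))
  expect_true(all(vapply(idx, anyDuplicated, integer(1)) == 0L))
  w <- attr(idx, "weights")[[1]]
  expect_true(all(w == w[1]))
  # determinism under the design seed
  idx2 <- sir_resample(cht, spec)
  expect_identical(idx, idx2)
})

test_that("gaussian SIR reproduces the target coordinate distribution", {
  set.seed(77)
  n_cohort <- 30000
  coords <- cbind(runif(n_cohort, 0, 100), runif(n_cohort, 0, 100))
  g <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, n_cohort))
  cht <- cohort(sprintf("i%05d", 1:n_cohort), coords, g)
  spec <- resample_spec(center = c(50, 50), width = 15, size = 2000,
                        replicates = 5, seed = 9, density_adjust = "hist")
  idx <- sir_resample(cht, spec)
  # moments over replicates
  xs <- coords[unlist(idx), 1]
  ys <- coords[unlist(idx), 2]
  expect_equal(mean(xs), 50, tolerance = 0.02)
  expect_equal(sd(ys), 15, tolerance = 0.05)
  # per-axis Kolmogorov-Smirnov against the target law on one replicate
  p_x <- suppressWarnings(ks.test(coords[idx[[1]], 1], "pnorm", 50, 15))$p.value
  p_y <- suppressWarnings(ks.test(coords[idx[[1]], 2], "pnorm", 50, 15))$p.value
  expect_gt(p_x, 0.01)
  expect_gt(p_y, 0.01)
  # a target too narrow for the cohort is refused with a diagnostic
  too_narrow <- resample_spec(center = c(50, 50), width = 1, size = 2000,
                              replicates = 1, seed = 1)
  expect_error(sir_resample(cht, too_narrow), "effective sample size")
})

test_that("cohort SFS counts alleles over the subsample", {
  n <- 10
  g <- Matrix::sparseMatrix(i = c(1, 2, 2), j = c(3, 3, 4), x = 1,
                            dims = c(4, n))
  cht <- cohort(sprintf("i%02d", 1:n),
                cbind(runif(n), runif(n)), g)
  # single individual carrying one variant: that site is a singleton
  sfs1 <- cohort_sfs(cht, indices = c(3, 5, 6))
  expect_equal(sfs1$counts[2], 2)  # sites 1 and 2 are singletons
  # all individuals: histogram of the genotype row sums
  sfs_all <- cohort_sfs(cht, seq_len(n))
  expect_equal(sfs_all$counts,
               tabulate(Matrix::rowSums(g) + 1, nbins = n + 1))
  expect_equal(sum(sfs_all$counts), 4)
  expect_error(cohort_sfs(cht, integer(0)), "empty")
  expect_error(cohort_sfs(cht, 99), "range")
})

test_that("synthetic cohorts have stationary carrier clusters per class", {
  pop <- pop_params(sigma = 3, rho = 0.5, mu = 2.5e-4, s = 0.1, L = 40)
  cht <- generate_synthetic_cohort(pop, s_classes = c(strong = 0.3,
                                                      weak = 0.1),
                                   sites_per_class = 160L, seed = 5)
  expect_s3_class(cht, "cohort")
  expect_equal(length(cht$ids), pop$N)
  expect_equal(nrow(cht$genotypes), 320)
  expect_equal(unique(cht$annotations$class), c("strong", "weak"))
  # per-class mean allele frequency ~ mu/s (single stationary snapshot:
  # the carrier total has relative sd 1/sqrt(Lambda); allow 3.5 sd)
  Lambda <- 160 * pop$N * pop$mu
  for (cl in c("strong", "weak")) {
    sites <- cht$annotations$site[cht$annotations$class == cl]
    s_cl <- cht$annotations$s[cht$annotations$class == cl][1]
    freq <- sum(cht$genotypes[sites, ]) / (pop$N * length(sites))
    expect_lt(abs(freq / (pop$mu / s_cl) - 1), 3.5 / sqrt(Lambda))
  }
  # determinism
  cht2 <- generate_synthetic_cohort(pop, s_classes = c(strong = 0.3,
                                                       weak = 0.1),
                                    sites_per_class = 160L, seed = 5)
  expect_identical(cht$coords, cht2$coords)
  expect_identical(cht$genotypes, cht2$genotypes)
  # zero mutation rate: all-zero genotype matrix
  pop0 <- pop_params(sigma = 3, rho = 0.5, mu = 0, s = 0.1, L = 40)
  cht0 <- generate_synthetic_cohort(pop0, s_classes = c(a = 0.3),
                                    sites_per_class = 10L, seed = 1)
  expect_equal(sum(cht0$genotypes), 0)
  # carriers exceeding the cohort size are refused
  popbig <- pop_params(sigma = 3, rho = 0.5, mu = 2.5e-4, s = 0.1, L = 40)
  expect_error(generate_synthetic_cohort(popbig, n_individuals = 10,
                                         s_classes = c(a = 0.1),
                                         sites_per_class = 200L, seed = 1),
               "exceed n_individuals")
})

test_that("a one-design one-replicate report equals the plain summary", {
  cht <- tiny_cohort(n = 400)
  spec <- resample_spec(size = 100, replicates = 1, seed = 8,
                        kind = "uniform")
  rep1 <- resampling_report(cht, list(spec))
  idx <- sir_resample(cht, spec)
  st <- summarize_sfs(cohort_sfs(cht, idx[[1]]))
  for (nm in c("variant_sites", "singletons", "mean_freq_all")) {
    expect_equal(rep1$mean[rep1$stat == nm], st[[nm]])
    expect_equal(rep1$sd[rep1$stat == nm], 0)
  }
  expect_true(all(rep1$pct_change_vs_first %in% c(0, NaN)))
})
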