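#' Simulation schedule for the spatial branching process
#'
#' @param pop A [pop_params()] object. The total mutation influx is
#'   `Lambda = n_sites * N * mu` new alleles per generation (each a fresh
#'   allele id at a uniform position — the infinite-sites convention; a
#'   single site receives new mutant lineages at rate `N * mu`).
#' @param total_time Simulated time span, generations.
#' @param burn_in Generations discarded before the first record; defaults to
#'   `10 / s`, about ten allele lifetimes, ample for stationarity.
#' @param record_every Spacing of record times, generations; defaults to
#'   `1 / s`, roughly one decorrelation time of the carrier configuration.
#' @param kernels List of [sampling_kernel()] objects scored at each record
#'   time.
#' @param seed RNG seed (mandatory: stochastic runs must be reproducible).
#' @param max_carriers Abort threshold on the carrier count; a run hitting it
#'   is in a parameter regime that violates the rarity assumption.
#' @param n_sites Number of sites whose mutational influx is simulated
#'   jointly (families are independent, so the run is statistically `n_sites`
#'   independent single-site runs).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pop, total_time, burn_in = 10 / pop$s,
                       record_every = 1 / pop$s,
                       kernels = list(sampling_kernel("uniform")),
                       seed, max_carriers = 1e6L, n_sites = 1) {
  stopifnot(inherits(pop, "pop_params"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an explicit numeric `seed` is required")
  if (!is.list(kernels) ||
      !all(vapply(kernels, inherits, logical(1), "sampling_kernel")))
    stop("`kernels` must be a list of sampling_kernel objects")
  if (burn_in >= total_time) stop("`burn_in` must be < `total_time`")
  if (record_every <= 0) stop("`record_every` must be > 0")
  if (n_sites < 1) stop("`n_sites` must be >= 1")
  structure(list(pop = pop, total_time = total_time, burn_in = burn_in,
                 record_every = record_every, kernels = kernels,
                 seed = as.integer(seed), max_carriers = as.integer(max_carriers),
                 n_sites = n_sites),
            class = "sim_config")
}

#' Run the spatial branching-process simulation
#'
#' Continuous-time Gillespie simulation of carriers of rare deleterious
#' alleles on the torus: mutation influx at rate `Lambda = n_sites * N * mu`
#' (each mutation founds a new allele at a uniform position), per-carrier
#' birth rate `1 - s` (offspring at the parent's position) and death rate 1,
#' with exact lazy Brownian dispersal between events. At each record time
#' after burn-in, the kernel-weighted frequency `x_w` of every extant allele
#' is scored against each configured kernel.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `branching_sim`: a list with
#'   \describe{
#'     \item{records}{data.frame with columns `time`, `kernel_id`,
#'       `allele_id`, `x_w` (one row per extant allele, kernel and record
#'       time; record times with no extant alleles contribute no rows but
#'       are listed in `times`).}
#'     \item{times}{all record times (needed to account for empty records).}
#'     \item{final}{data.frame of final carrier states (`allele_id`, `x`,
#'       `y`) at `total_time`.}
#'     \item{n_events, n_alleles_total, config}{bookkeeping.}
#'   }
#' @examples
#' pop <- pop_params(sigma = 2, rho = 20, mu = 2.5e-9, s = 0.5, L = 1000)
#' cfg <- sim_config(pop, total_time = 40, seed = 1)  # Lambda = N*mu = 0.05
#' sim <- run_branching(cfg)
#' @export
run_branching <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pop <- config$pop
  Lambda <- config$n_sites * pop$N * pop$mu
  set.seed(config$seed)
  raw <- gillespie_branching_cpp(Lambda, pop$s, pop$sigma, pop$L,
                                 config$total_time, config$burn_in,
                                 config$record_every, config$max_carriers,
                                 0L)
  recs <- score_snapshots(raw$times, raw$snapshots, config$kernels, pop)
  structure(list(
    records = recs,
    times = raw$times,
    final = data.frame(allele_id = raw$final$allele,
                       x = raw$final$x, y = raw$final$y),
    n_events = raw$n_events,
    n_alleles_total = raw$n_alleles_total,
    config = config
  ), class = "branching_sim")
}

# Score carrier snapshots against each kernel: per allele,
# x_w = (1/rho) * sum_i kernel_density(position_i).
score_snapshots <- function(times, snapshots, kernels, pop) {
  out <- vector("list", length(times) * length(kernels))
  idx <- 0L
  for (ti in seq_along(times)) {
    snap <- snapshots[[ti]]
    if (length(snap$allele) == 0L) next
    pos <- cbind(snap$x, snap$y)
    for (ki in seq_along(kernels)) {
      dens <- kernel_density(kernels[[ki]], pos, pop$L)
      xw <- rowsum(dens, group = snap$allele) / pop$rho
      idx <- idx + 1L
      out[[idx]] <- data.frame(rec = ti, time = times[ti], kernel_id = ki,
                               allele_id = as.integer(rownames(xw)),
                               x_w = as.numeric(xw))
    }
  }
  if (idx == 0L)
    return(data.frame(rec = integer(), time = numeric(), kernel_id = integer(),
                      allele_id = integer(), x_w = numeric()))
  do.call(rbind, out[seq_len(idx)])
}

#' @method print branching_sim
#' @export
print.branching_sim <- function(x, ...) {
  cat(sprintf(
    "Spatial branching simulation: %d record times, %d kernels, %g events\n",
    length(x$times), length(x$config$kernels), x$n_events))
  cat(sprintf("  alleles ever arisen: %d; carriers at end: %d\n",
              x$n_alleles_total, nrow(x$final)))
  invisible(x)
}

#' Kernel-weighted allele frequency of a carrier configuration
#'
#' `x_w = (1/rho) * sum_i kernel_density(position_i)` over the carriers of
#' one allele. For the uniform kernel this reduces to
#' `(number of carriers) / N`.
#'
#' @param positions n x 2 matrix (or length-2 vector) of carrier positions.
#' @param kernel A [sampling_kernel()] object.
#' @param pop A [pop_params()] object.
#' @return The weighted frequency (0 for an empty configuration).
#' @export
weighted_frequency <- function(positions, kernel, pop) {
  stopifnot(inherits(kernel, "sampling_kernel"), inherits(pop, "pop_params"))
  if (is.null(positions) || length(positions) == 0L) return(0)
  positions <- matrix(as.numeric(positions), ncol = 2)
  sum(kernel_density(kernel, positions, pop$L)) / pop$rho
}

#' Poisson sampling of an allele count from a weighted frequency
#'
#' The number of copies of an allele with weighted population frequency
#' `x_w` observed in a sample of size `n` follows `Poisson(n * x_w)` (the
#' Poisson approximation to binomial sampling, appropriate for rare
#' alleles).
#'
#' @param x_w Weighted frequency (>= 0), vectorised.
#' @param n Sample size.
#' @return Integer draw(s) `K`.
#' @export
sample_allele_count <- function(x_w, n) {
  stopifnot(is.numeric(x_w), all(x_w >= 0), n >= 1)
  stats::rpois(length(x_w), n * x_w)
}

#' Per-site weighted-frequency series from simulation records
#'
#' Sum the per-allele weighted frequencies at each record time (zeros for
#' record times with no extant allele) and divide by the number of sites
#' simulated: the result is the per-site frequency series X(t), whose
#' stationary distribution the theory approximates by
#' Gamma(theta_E, gamma_E).
#'
#' @param sim A [run_branching()] result.
#' @param kernel_id Which configured kernel to extract.
#' @return Numeric vector, one value per record time.
#' @export
site_frequency_series <- function(sim, kernel_id = 1L) {
  stopifnot(inherits(sim, "branching_sim"))
  X <- numeric(length(sim$times))
  r <- sim$records[sim$records$kernel_id == kernel_id, ]
  if (nrow(r)) {
    agg <- rowsum(r$x_w, group = r$rec)
    X[as.integer(rownames(agg))] <- agg
  }
  X / sim$config$n_sites
}

#' Estimate effective SFS parameters from simulated frequencies
#'
#' Method-of-moments gamma fit to the per-site weighted-frequency series
#' X(t): with mean `m` and variance `v`, `theta_hat = m^2 / v` and
#' `gamma_hat = m / v`. The atom at zero is included by default (record
#' times with no segregating allele enter as X = 0); with
#' `include_zero = FALSE` the fit is restricted to segregating records
#' (X > 0) only. Standard errors come from a moving-block bootstrap over
#' record times, which respects the serial correlation of the series.
#'
#' @param sim A [run_branching()] result, or a numeric frequency series.
#' @param kernel_id Kernel to estimate for (when `sim` is a simulation).
#' @param include_zero Include the zero-frequency records (default) or
#'   restrict to segregating mass.
#' @param block_len Bootstrap block length, in records.
#' @param n_boot Number of bootstrap resamples.
#' @return A list with `theta_hat`, `gamma_hat`, `se_theta`, `se_gamma`,
#'   `mean`, `var`, `n_records`.
#' @export
estimate_effective_params <- function(sim, kernel_id = 1L,
                                      include_zero = TRUE,
                                      block_len = 10L, n_boot = 200L) {
  X <- if (inherits(sim, "branching_sim"))
    site_frequency_series(sim, kernel_id) else as.numeric(sim)
  if (!include_zero) X <- X[X > 0]
  if (length(X) < 2L) stop("need at least 2 records")
  mom <- function(x) {
    m <- mean(x); v <- stats::var(x)
    if (v <= 0) stop("zero variance in frequency series: cannot fit gamma")
    c(theta = m^2 / v, gamma = m / v)
  }
  est <- mom(X)
  nb <- length(X)
  block_len <- max(1L, min(block_len, nb - 1L))
  n_blocks <- ceiling(nb / block_len)
  boot <- matrix(NA_real_, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    starts <- sample.int(nb - block_len + 1L, n_blocks, replace = TRUE)
    idx <- as.vector(outer(0:(block_len - 1L), starts, `+`))[seq_len(nb)]
    bo <- tryCatch(mom(X[idx]), error = function(e) c(NA_real_, NA_real_))
    boot[b, ] <- bo
  }
  list(theta_hat = unname(est["theta"]), gamma_hat = unname(est["gamma"]),
       se_theta = stats::sd(boot[, 1], na.rm = TRUE),
       se_gamma = stats::sd(boot[, 2], na.rm = TRUE),
       mean = mean(X), var = stats::var(X), n_records = nb)
}

#' Build a sample SFS from simulation records
#'
#' At a chosen record time, draw a Poisson(n * x_w) allele count for every
#' extant allele (each allele is one site under infinite sites) and
#' histogram the counts; the remaining `M - (number of extant alleles)`
#' surveyed sites are monomorphic and fill the k = 0 class.
#'
#' @param sim A [run_branching()] result.
#' @param n Sample size.
#' @param M Total number of surveyed sites; must be at least the number of
#'   extant alleles at the chosen time.
#' @param kernel_id Kernel whose weighted frequencies are sampled.
#' @param rec Index of the record time to use (default: the last one).
#' @return A [sample_sfs()] object.
#' @export
build_sim_sfs <- function(sim, n, M, kernel_id = 1L, rec = NULL) {
  stopifnot(inherits(sim, "branching_sim"))
  if (length(sim$times) < 1L) stop("simulation has no record times")
  if (is.null(rec)) rec <- length(sim$times)
  r <- sim$records[sim$records$kernel_id == kernel_id &
                     sim$records$rec == rec, ]
  if (nrow(r) > M)
    stop(sprintf("M = %d is smaller than the %d segregating alleles at t = %g",
                 M, nrow(r), sim$times[rec]))
  k <- if (nrow(r)) sample_allele_count(r$x_w, n) else integer(0)
  k <- pmin(k, n)  # a site cannot exceed the sample size in an observed SFS
  counts <- table(factor(k, levels = 0:n))
  counts[1] <- counts[1] + (M - nrow(r))
  sample_sfs(n = n, M = M, counts = as.integer(counts), k = 0:n)
}
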