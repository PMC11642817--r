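#' Sample site frequency spectrum
#'
#' Container for an observed (unfolded) sample SFS: for each derived-allele
#' count `k` in `0..n`, the number of surveyed sites at that count. The
#' monomorphic class `k = 0` is part of the spectrum, so the counts sum to
#' the total number of surveyed sites `M`.
#'
#' @param n Haploid sample size.
#' @param M Total surveyed sites (monomorphic included).
#' @param counts Site counts; either a full vector aligned with `k`, or a
#'   sparse set matched to the `k` given.
#' @param k Allele counts corresponding to `counts` (default `0:n`).
#' @return An object of class `sample_sfs` with fields `n`, `M` and a full
#'   counts vector indexed `0..n`.
#' @examples
#' sfs <- sample_sfs(n = 4, M = 3, counts = c(1, 1, 1), k = 0:2)
#' summarize_sfs(sfs)
#' @export
sample_sfs <- function(n, M, counts, k = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            is.numeric(M), length(M) == 1L, M >= 0, M == round(M))
  if (is.null(k)) k <- seq_along(counts) - 1L
  stopifnot(length(k) == length(counts), all(k >= 0), all(k <= n),
            all(counts >= 0), all(counts == round(counts)),
            !anyDuplicated(k))
  full <- numeric(n + 1)
  full[k + 1] <- counts
  if (abs(sum(full) - M) > 0.5)
    stop(sprintf("counts sum to %g but M = %g", sum(full), M))
  structure(list(n = as.integer(n), M = M, counts = full),
            class = "sample_sfs")
}

#' @method print sample_sfs
#' @export
print.sample_sfs <- function(x, ...) {
  seg <- sum(x$counts[-1])
  cat(sprintf("Sample SFS: n = %d, M = %g sites (%g variant, %g singletons)\n",
              x$n, x$M, seg, x$counts[2]))
  invisible(x)
}

#' Summary statistics of an observed sample SFS
#'
#' Computes the statistics through which the discovery and dilution effects
#' of sampling breadth are read off a spectrum: the number and proportion of
#' variant sites, the number of singletons, the mean allele frequency at
#' variant sites versus over all sites, the mean per-site heterozygosity
#' `2 (k/n)(1 - k/n)`, and the cumulative minor-allele frequency (folding at
#' `n/2`, the burden-test dosage scale).
#'
#' @param sfs A [sample_sfs()] object.
#' @return A one-row data.frame with columns `n`, `M`, `variant_sites`,
#'   `singletons`, `prop_variant`, `prop_singleton`, `mean_freq_variant`
#'   (NA when there are no variant sites), `mean_freq_all`, `het`, `cmaf`.
#' @export
summarize_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sample_sfs"))
  n <- sfs$n
  k <- 0:n
  cnt <- sfs$counts
  variant_sites <- sum(cnt[-1])
  singletons <- cnt[2]
  total_copies <- sum(k * cnt)
  data.frame(
    n = n, M = sfs$M,
    variant_sites = variant_sites,
    singletons = singletons,
    prop_variant = variant_sites / sfs$M,
    prop_singleton = singletons / sfs$M,
    mean_freq_variant = if (variant_sites > 0)
      total_copies / (n * variant_sites) else NA_real_,
    mean_freq_all = total_copies / (n * sfs$M),
    het = sum(cnt * 2 * (k / n) * (1 - k / n)) / sfs$M,
    cmaf = sum(pmin(k, n - k) * cnt) / n
  )
}

#' Theoretical sample SFS as a spectrum table
#'
#' Evaluate the negative-binomial finite-sample SFS over `k = 0..kmax` as a
#' normalized spectrum (probabilities per site), the analytic counterpart of
#' an observed [sample_sfs()] divided by `M`.
#'
#' @param eff An [eff_params()] object.
#' @param n Sample size.
#' @param kmax Largest allele count tabulated.
#' @return data.frame with columns `k`, `prob`.
#' @export
theory_sfs <- function(eff, n, kmax = 100L) {
  data.frame(k = 0:kmax, prob = sfs_pmf(eff, n, 0:kmax))
}

# normalized spectrum (k, prob, n) from either representation
as_spectrum <- function(x) {
  if (inherits(x, "sample_sfs")) {
    data.frame(k = 0:x$n, prob = x$counts / x$M, n = x$n)
  } else if (is.data.frame(x) && all(c("k", "prob") %in% names(x))) {
    x$n <- attr(x, "n", exact = TRUE) %||% NA_integer_
    x
  } else stop("expected a sample_sfs or a data.frame with columns k, prob")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ratio between two site frequency spectra
#'
#' Elementwise ratio of the normalized entries of two spectra over their
#' shared support of variant counts, with zero-denominator entries flagged
#' (`NA` ratio). The crossover count `k*` — the smallest `k` at which the
#' ratio first reaches 1 from below — locates the boundary between the
#' regime where spectrum `a` has relatively fewer sites (small `k`,
#' discovery deficit) and the regime where it has relatively more
#' (concentration at larger `k`).
#'
#' @param sfs_a,sfs_b [sample_sfs()] objects or data.frames with columns
#'   `k`, `prob` (e.g. from [theory_sfs()]). Observed spectra must share the
#'   sample size `n`; normalized theory spectra are comparable as-is.
#' @return An object of class `sfs_ratio`: data.frame with columns `k`,
#'   `prob_a`, `prob_b`, `ratio`, plus attribute `crossover` (`k*`, NA if
#'   the ratio never crosses 1).
#' @export
sfs_ratio <- function(sfs_a, sfs_b) {
  a <- as_spectrum(sfs_a)
  b <- as_spectrum(sfs_b)
  if (!is.na(a$n[1]) && !is.na(b$n[1]) && a$n[1] != b$n[1])
    stop("spectra have different sample sizes; normalize or resample first")
  kk <- intersect(a$k, b$k)
  kk <- sort(kk[kk >= 1])
  if (length(kk) == 0L) stop("no shared variant counts to compare")
  pa <- a$prob[match(kk, a$k)]
  pb <- b$prob[match(kk, b$k)]
  ratio <- ifelse(pb > 0, pa / pb, NA_real_)
  ok <- !is.na(ratio)
  cross <- NA_real_
  if (any(ok) && any(ratio[ok] < 1) && any(ratio[ok] > 1)) {
    below <- kk[ok][ratio[ok] < 1]
    above <- kk[ok][ratio[ok] > 1]
    if (length(below) && length(above) && min(below) < min(above))
      cross <- min(above)
  }
  structure(data.frame(k = kk, prob_a = pa, prob_b = pb, ratio = ratio),
            crossover = cross, class = c("sfs_ratio", "data.frame"))
}
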