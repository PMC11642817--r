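#' Cohort of located, genotyped individuals
#'
#' Container for the resampling pipeline: per-individual 2-D coordinates
#' (geographic or PC-like space) aligned with the columns of a haploid 0/1
#' genotype matrix (sites in rows), plus optional per-site annotations such
#' as the selection class a synthetic site was generated under.
#'
#' @param ids Character vector of individual identifiers.
#' @param coords n x 2 numeric matrix of coordinates, rows aligned to `ids`.
#' @param genotypes sites x individuals matrix (base or `Matrix` sparse)
#'   with entries in \{0, 1\}.
#' @param annotations Optional data.frame with one row per site.
#' @return An object of class `cohort`.
#' @export
cohort <- function(ids, coords, genotypes, annotations = NULL) {
  coords <- as.matrix(coords)
  stopifnot(is.character(ids), ncol(coords) == 2L,
            nrow(coords) == length(ids),
            ncol(genotypes) == length(ids))
  rng <- suppressWarnings(range(genotypes))
  if (length(genotypes) > 0 && (rng[1] < 0 || rng[2] > 1))
    stop("genotype entries must be 0/1")
  if (!is.null(annotations) && nrow(annotations) != nrow(genotypes))
    stop("annotations must have one row per site")
  structure(list(ids = ids, coords = coords, genotypes = genotypes,
                 annotations = annotations),
            class = "cohort")
}

#' @method print cohort
#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals, %d sites (%d segregating)\n",
              length(x$ids), nrow(x$genotypes),
              sum(Matrix::rowSums(x$genotypes) > 0)))
  invisible(x)
}

#' Empirical sampling-density estimate at each individual's coordinate
#'
#' Estimates the density of the cohort's coordinate distribution at every
#' individual, the denominator of the SIR importance weights (it corrects
#' for heterogeneity in how the cohort itself was collected). The default
#' is a 2-D Gaussian product-kernel density estimate on a grid with the
#' normal-reference plug-in bandwidth, bilinearly interpolated back to the
#' points; `method = "hist"` uses a 2-D histogram (cheap and robust for
#' gridded synthetic cohorts).
#'
#' @param coords n x 2 matrix of coordinates (n >= 2, not all identical).
#' @param method `"kde"` or `"hist"`.
#' @param gridsize Grid resolution per axis (kde) or bin count (hist).
#' @return Positive density estimate at each coordinate, with the method
#'   recorded in attribute `"method"`.
#' @export
estimate_sampling_density <- function(coords, method = c("kde", "hist"),
                                      gridsize = 128L) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  if (nrow(coords) < 2L) stop("need at least 2 individuals")
  if (stats::sd(coords[, 1]) == 0 && stats::sd(coords[, 2]) == 0)
    stop("degenerate coordinates: all individuals at the same point")
  if (method == "kde") {
    bw <- c(MASS::bandwidth.nrd(coords[, 1]), MASS::bandwidth.nrd(coords[, 2]))
    bw[bw <= 0] <- max(bw, 1e-8)
    pad <- 0.1 * c(diff(range(coords[, 1])), diff(range(coords[, 2]))) + bw
    kd <- MASS::kde2d(coords[, 1], coords[, 2], h = bw, n = gridsize,
                      lims = c(range(coords[, 1]) + c(-1, 1) * pad[1],
                               range(coords[, 2]) + c(-1, 1) * pad[2]))
    dens <- bilinear_at(kd$x, kd$y, kd$z, coords)
  } else {
    bx <- seq(min(coords[, 1]), max(coords[, 1]), length.out = gridsize + 1L)
    by <- seq(min(coords[, 2]), max(coords[, 2]), length.out = gridsize + 1L)
    ix <- pmin(pmax(findInterval(coords[, 1], bx, all.inside = TRUE), 1L),
               gridsize)
    iy <- pmin(pmax(findInterval(coords[, 2], by, all.inside = TRUE), 1L),
               gridsize)
    tab <- table(factor(ix, levels = 1:gridsize),
                 factor(iy, levels = 1:gridsize))
    area <- diff(bx)[1] * diff(by)[1]
    dens <- tab[cbind(ix, iy)] / (nrow(coords) * area)
  }
  dens <- pmax(as.numeric(dens), 1e-300)
  attr(dens, "method") <- method
  dens
}

bilinear_at <- function(gx, gy, gz, p) {
  ix <- pmin(pmax(findInterval(p[, 1], gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(p[, 2], gy), 1L), length(gy) - 1L)
  fx <- (p[, 1] - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (p[, 2] - gy[iy]) / (gy[iy + 1L] - gy[iy])
  fx <- pmin(pmax(fx, 0), 1)
  fy <- pmin(pmax(fy, 0), 1)
  gz[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    gz[cbind(ix + 1L, iy)] * fx * (1 - fy) +
    gz[cbind(ix, iy + 1L)] * (1 - fx) * fy +
    gz[cbind(ix + 1L, iy + 1L)] * fx * fy
}

#' Resampling design
#'
#' A target sampling distribution in the cohort's coordinate space: a 2-D
#' Gaussian of standard deviation `width` at `center`, or a uniform target
#' under which the resample is a simple random sample. Several centres may
#' be given (one per row); replicates then cycle through them, so summary
#' statistics averaged over replicates also average over the quenched
#' spatial fluctuations of any one neighbourhood, and their SD includes the
#' between-centre variance.
#'
#' @param center Length-2 target centre, or a k x 2 matrix of centres
#'   (ignored for uniform).
#' @param width Target Gaussian SD, in coordinate units; `NULL` with
#'   `kind = "uniform"`.
#' @param size Subsample size per replicate.
#' @param replicates Number of replicate subsamples.
#' @param seed RNG seed (mandatory).
#' @param kind `"gaussian"` or `"uniform"`.
#' @param density_adjust Method tag for the empirical-density correction,
#'   passed to [estimate_sampling_density()].
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(center = c(0, 0), width = NULL, size,
                          replicates = 1L, seed,
                          kind = c("gaussian", "uniform"),
                          density_adjust = c("kde", "hist")) {
  kind <- match.arg(kind)
  density_adjust <- match.arg(density_adjust)
  if (missing(seed)) stop("an explicit `seed` is required")
  if (kind == "gaussian" && (is.null(width) || width <= 0))
    stop("gaussian target requires `width` > 0")
  center <- if (is.matrix(center)) center else matrix(center, nrow = 1)
  stopifnot(ncol(center) == 2L)
  structure(list(center = center,
                 width = if (kind == "gaussian") width else NA_real_,
                 size = as.integer(size), replicates = as.integer(replicates),
                 seed = as.integer(seed), kind = kind,
                 density_adjust = density_adjust),
            class = "resample_spec")
}

#' Sampling importance resampling of a cohort
#'
#' Constructs spatially concentrated subsamples whose coordinate
#' distribution approximates the target of the design: each individual gets
#' an importance weight proportional to
#' `target_density(coords) / empirical_density(coords)`, and each replicate
#' is drawn without replacement by sequential weighted selection with
#' inclusion probabilities proportional to the weights. A uniform target on
#' any cohort reduces to a simple random sample.
#'
#' @param cht A [cohort()] object.
#' @param spec A [resample_spec()] design.
#' @param density Optional precomputed empirical density (from
#'   [estimate_sampling_density()]); estimated from the cohort if missing.
#' @return List of integer index vectors, one per replicate. The importance
#'   weights and their effective sample size are attached as attributes
#'   `"weights"` and `"ess"`.
#' @export
sir_resample <- function(cht, spec, density = NULL) {
  stopifnot(inherits(cht, "cohort"), inherits(spec, "resample_spec"))
  n_cohort <- length(cht$ids)
  if (spec$size > n_cohort) stop("subsample size exceeds cohort size")
  if (spec$kind == "uniform") {
    w_list <- list(rep(1 / n_cohort, n_cohort))
  } else {
    if (is.null(density))
      density <- estimate_sampling_density(cht$coords,
                                           method = spec$density_adjust)
    w_list <- lapply(seq_len(nrow(spec$center)), function(ci) {
      target <- stats::dnorm(cht$coords[, 1], spec$center[ci, 1],
                             spec$width) *
        stats::dnorm(cht$coords[, 2], spec$center[ci, 2], spec$width)
      w <- target / density
      w / sum(w)
    })
    ess <- vapply(w_list, function(w) 1 / sum(w^2), numeric(1))
    if (any(ess < spec$size))
      stop(sprintf(paste0(
        "effective sample size of importance weights (%.0f) is below the ",
        "requested subsample size (%d): the target (width %g) is too ",
        "narrow for this cohort"), min(ess), spec$size, spec$width))
  }
  set.seed(spec$seed)
  out <- lapply(seq_len(spec$replicates), function(r) {
    w <- w_list[[(r - 1L) %% length(w_list) + 1L]]  # cycle through centres
    sort(sample.int(n_cohort, spec$size, replace = FALSE, prob = w))
  })
  attr(out, "weights") <- w_list
  attr(out, "ess") <- min(vapply(w_list, function(w) 1 / sum(w^2),
                                 numeric(1)))
  out
}

#' Sample SFS of a cohort subsample
#'
#' Per-site derived-allele counts over the selected individuals,
#' histogrammed into a [sample_sfs()] with `n` the subsample size and `M`
#' the number of sites considered.
#'
#' @param cht A [cohort()] object.
#' @param indices Integer indices of the subsampled individuals.
#' @param sites Optional integer subset of sites (default: all).
#' @return A [sample_sfs()] object.
#' @export
cohort_sfs <- function(cht, indices, sites = NULL) {
  stopifnot(inherits(cht, "cohort"))
  if (length(indices) == 0L) stop("empty subsample")
  if (any(indices < 1L | indices > length(cht$ids)))
    stop("indices out of range")
  g <- cht$genotypes[, indices, drop = FALSE]
  if (!is.null(sites)) g <- g[sites, , drop = FALSE]
  kcount <- as.numeric(Matrix::rowSums(g))
  n <- length(indices)
  counts <- tabulate(kcount + 1L, nbins = n + 1L)
  sample_sfs(n = n, M = nrow(g), counts = counts, k = 0:n)
}

#' Generate a synthetic cohort with spatially clustered rare carriers
#'
#' Stands in for a real biobank cohort: for each selection class, the
#' spatial branching process is run to stationarity for `sites_per_class`
#' sites. The cohort's `n_individuals` are placed uniformly (the model's
#' constant-density population), and every carrier present at the end of a
#' class run is assigned to the nearest individual (per-site unique), which
#' receives genotype 1 at the carrier's site. Individuals can therefore
#' carry variants at several sites, carrier counts are preserved exactly,
#' and the cohort's coordinate distribution is exactly uniform. Per-site
#' true selection coefficients are recorded in the annotations, mimicking
#' annotation severity classes (e.g. LoF / missense / synonymous) by `s`
#' alone.
#'
#' @param pop A [pop_params()] object supplying `sigma`, `rho`, `mu`, `L`
#'   (its `s` is replaced per class); `n_individuals` defaults to the total
#'   population size `N = rho * L^2`.
#' @param n_individuals Number of cohort individuals.
#' @param s_classes Named numeric vector of selection coefficients, one per
#'   site class, strongest first.
#' @param sites_per_class Number of surveyed sites per class (segregating
#'   plus monomorphic).
#' @param seed RNG seed.
#' @return A [cohort()] object with annotations columns `site`, `class`,
#'   `s`.
#' @export
generate_synthetic_cohort <- function(pop, n_individuals = pop$N,
                                      s_classes = c(lof = 0.02,
                                                    missense = 0.01,
                                                    synonymous = 0.002),
                                      sites_per_class = 1600L, seed) {
  stopifnot(inherits(pop, "pop_params"))
  if (missing(seed)) stop("an explicit `seed` is required")
  if (is.null(names(s_classes)))
    names(s_classes) <- paste0("class", seq_along(s_classes))
  carrier_pos <- list(); carrier_site <- list()
  ann <- list()
  site_offset <- 0L
  for (ci in seq_along(s_classes)) {
    s_c <- s_classes[[ci]]
    if (pop$mu > 0) {
      pop_c <- pop_params(pop$sigma, pop$rho, pop$mu, s_c, pop$L)
      cfg <- sim_config(pop_c, total_time = 11 / s_c, burn_in = 10 / s_c,
                        record_every = 1 / s_c, seed = seed + ci,
                        n_sites = sites_per_class)
      sim <- run_branching(cfg)
      fin <- sim$final
    } else {
      fin <- data.frame(allele_id = integer(), x = numeric(), y = numeric())
    }
    alleles <- sort(unique(fin$allele_id))
    if (length(alleles) > sites_per_class)
      stop(sprintf(
        "class %s: %d segregating alleles exceed sites_per_class = %d",
        names(s_classes)[ci], length(alleles), sites_per_class))
    carrier_pos[[ci]] <- cbind(fin$x, fin$y)
    carrier_site[[ci]] <- site_offset + match(fin$allele_id, alleles)
    ann[[ci]] <- data.frame(site = site_offset + seq_len(sites_per_class),
                            class = names(s_classes)[ci], s = s_c)
    site_offset <- site_offset + sites_per_class
  }
  pos <- do.call(rbind, carrier_pos)
  site_of_carrier <- unlist(carrier_site)
  n_carriers <- if (is.null(pos)) 0L else nrow(pos)
  if (n_carriers > 0L && max(tabulate(site_of_carrier)) > n_individuals)
    stop(sprintf(
      "a site carries %d copies, which exceed n_individuals = %d",
      max(tabulate(site_of_carrier)), n_individuals))
  # the cohort itself is uniformly distributed (the model's population is a
  # constant-density background); each simulated carrier is assigned to the
  # nearest individual, so carrier counts are preserved exactly and the
  # positional displacement is ~half the inter-individual spacing
  set.seed(seed)
  coords <- cbind(stats::runif(n_individuals, 0, pop$L),
                  stats::runif(n_individuals, 0, pop$L))
  M_total <- site_offset
  if (n_carriers > 0L) {
    carrier_col <- nearest_individual(pos, site_of_carrier, coords, pop$L)
    geno <- Matrix::sparseMatrix(
      i = site_of_carrier, j = carrier_col, x = 1,
      dims = c(M_total, n_individuals))
  } else {
    geno <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(M_total, n_individuals))
  }
  cohort(ids = sprintf("ind%06d", seq_len(n_individuals)),
         coords = coords, genotypes = geno,
         annotations = do.call(rbind, ann))
}

# Map each carrier position to the nearest cohort individual on the torus,
# never assigning the same individual twice for the same site (two carriers
# of one allele remain two carrier individuals). Grid-bucketed search:
# expected O(1) candidates per query at uniform density.
nearest_individual <- function(pos, site_of, coords, L) {
  n <- nrow(coords)
  ncell <- max(1L, floor(sqrt(n / 4)))
  cw <- L / ncell
  cx <- pmin(floor(coords[, 1] / cw), ncell - 1L)
  cy <- pmin(floor(coords[, 2] / cw), ncell - 1L)
  cell_of <- cx + ncell * cy + 1L
  bucket <- split(seq_len(n), cell_of)
  out <- integer(nrow(pos))
  taken <- new.env(parent = emptyenv())  # site -> assigned individuals
  for (i in seq_len(nrow(pos))) {
    px <- pos[i, 1]; py <- pos[i, 2]
    key <- as.character(site_of[i])
    used <- taken[[key]]
    ci <- pmin(floor(px / cw), ncell - 1L)
    cj <- pmin(floor(py / cw), ncell - 1L)
    best <- NA_integer_; bestd <- Inf
    for (ring in 0:ncell) {
      if (ring == 0L) {
        off <- cbind(0L, 0L)
      } else {
        off <- rbind(cbind(-ring:ring, -ring), cbind(-ring:ring, ring),
                     cbind(-ring, -(ring - 1L):(ring - 1L)),
                     cbind(ring, -(ring - 1L):(ring - 1L)))
      }
      cells <- ((ci + off[, 1]) %% ncell) + ncell * ((cj + off[, 2]) %% ncell) + 1L
      cand <- unlist(bucket[as.character(unique(cells))], use.names = FALSE)
      cand <- setdiff(cand, used)
      if (length(cand)) {
        d <- torus_distance(cbind(px, py), coords[cand, , drop = FALSE], L)
        j <- which.min(d)
        if (d[j] < bestd) { bestd <- d[j]; best <- cand[j] }
      }
      # once a hit lies within `ring` whole cells it cannot be beaten later
      if (!is.na(best) && bestd <= ring * cw) break
    }
    out[i] <- best
    taken[[key]] <- c(used, best)
  }
  out
}

#' Summary report over a set of resampling designs
#'
#' Runs each design through [sir_resample()], computes [summarize_sfs()]
#' per replicate and per site class, and tabulates the mean and SD over
#' replicates together with the percent change of each mean relative to
#' the first (narrowest) design.
#'
#' @param cht A [cohort()] object (annotations column `class` defines site
#'   classes; a single pseudo-class `"all"` is used when absent).
#' @param specs List of [resample_spec()] designs, narrowest first.
#' @return data.frame with columns `design`, `width`, `class`, `stat`,
#'   `mean`, `sd`, `pct_change_vs_first`.
#' @export
resampling_report <- function(cht, specs) {
  stopifnot(inherits(cht, "cohort"), is.list(specs), length(specs) >= 1L)
  classes <- if (!is.null(cht$annotations$class))
    unique(cht$annotations$class) else "all"
  dens <- if (any(vapply(specs, function(s) s$kind == "gaussian", logical(1))))
    estimate_sampling_density(cht$coords, method = specs[[1]]$density_adjust)
  else NULL
  stats_keep <- c("variant_sites", "singletons", "prop_variant",
                  "mean_freq_variant", "mean_freq_all", "het", "cmaf")
  rows <- list()
  for (di in seq_along(specs)) {
    spec <- specs[[di]]
    idx_sets <- sir_resample(cht, spec, density = dens)
    for (cl in classes) {
      sites <- if (identical(classes, "all")) NULL
        else which(cht$annotations$class == cl)
      per_rep <- do.call(rbind, lapply(idx_sets, function(idx)
        summarize_sfs(cohort_sfs(cht, idx, sites = sites))))
      for (st in stats_keep) {
        v <- per_rep[[st]]
        rows[[length(rows) + 1L]] <- data.frame(
          design = di, width = spec$width, class = cl, stat = st,
          mean = mean(v, na.rm = TRUE),
          sd = if (length(v) > 1L) stats::sd(v, na.rm = TRUE) else 0)
      }
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$design == 1L, c("class", "stat", "mean")]
  names(base)[3] <- "base_mean"
  out <- merge(out, base, by = c("class", "stat"), sort = FALSE)
  out$pct_change_vs_first <-
    100 * (out$mean - out$base_mean) / abs(out$base_mean)
  out$base_mean <- NULL
  out[order(out$design, out$class, out$stat), ]
}
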