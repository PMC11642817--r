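pkg_version <- function() {
  as.character(utils::packageVersion("spatsfs"))
}

# "#! key = value" provenance header lines
format_provenance <- function(params) {
  c(sprintf("#! tool = spatsfs %s", pkg_version()),
    vapply(names(params), function(k)
      sprintf("#! %s = %s", k, format(params[[k]], digits = 17)),
      character(1)))
}

parse_provenance_lines <- function(lines) {
  lines <- sub("^#!\\s*", "", lines)
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) out[[trimws(kv[2])]] <- coerce_scalar(kv[3])
  }
  out
}

coerce_scalar <- function(v) {
  v <- trimws(v)
  if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num) && !is.na(v) && grepl("^[-+0-9.eE]+$", v)) return(num)
  v
}

write_tsv_provenance <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_provenance(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#!", lines)
  body <- lines[!hdr]
  if (length(body) < 2L)
    stop(sprintf("%s: no data rows after provenance header", path))
  df <- tryCatch(
    utils::read.table(text = body, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e)
      stop(sprintf("%s: malformed table near line %d: %s",
                   path, sum(hdr) + 1L, conditionMessage(e))))
  attr(df, "provenance") <- parse_provenance_lines(lines[hdr])
  df
}

#' Write / read a sample SFS as TSV
#'
#' Tab-separated spectrum with columns `k`, `count`, `prob` and a
#' `#!`-prefixed provenance header carrying `n`, `M` and any extra
#' parameters, so the spectrum can be regenerated from the file alone.
#' Writing an empty spectrum (`M = 0`) is rejected.
#'
#' @param sfs A [sample_sfs()] object.
#' @param path Output/input file path.
#' @param params Named list of extra provenance entries.
#' @return `write_sfs_tsv` the path, invisibly; `read_sfs_tsv` a
#'   [sample_sfs()] with the parsed provenance attached as attribute
#'   `"provenance"`.
#' @export
write_sfs_tsv <- function(sfs, path, params = list()) {
  stopifnot(inherits(sfs, "sample_sfs"))
  if (sfs$M <= 0) stop("refusing to write an empty SFS (M = 0)")
  df <- data.frame(k = 0:sfs$n, count = sfs$counts,
                   prob = sfs$counts / sfs$M)
  write_tsv_provenance(df, path, c(list(n = sfs$n, M = sfs$M), params))
}

#' @rdname write_sfs_tsv
#' @export
read_sfs_tsv <- function(path) {
  df <- read_tsv_provenance(path)
  prov <- attr(df, "provenance")
  if (is.null(prov$n) || is.null(prov$M))
    stop(sprintf("%s: provenance header lacks n or M", path))
  sfs <- sample_sfs(n = prov$n, M = prov$M, counts = df$count, k = df$k)
  attr(sfs, "provenance") <- prov
  sfs
}

#' Write / read cohort coordinates as TSV
#'
#' Columns `id`, `x`, `y` with a provenance header.
#'
#' @param cht A [cohort()] object (or any list with `ids` and `coords`).
#' @param path File path.
#' @param params Extra provenance entries.
#' @return The path invisibly / a data.frame with columns `id`, `x`, `y`.
#' @export
write_coords_tsv <- function(cht, path, params = list()) {
  df <- data.frame(id = cht$ids, x = cht$coords[, 1], y = cht$coords[, 2])
  write_tsv_provenance(df, path, params)
}

#' @rdname write_coords_tsv
#' @export
read_coords_tsv <- function(path) {
  df <- read_tsv_provenance(path)
  if (!all(c("id", "x", "y") %in% names(df)))
    stop(sprintf("%s: expected columns id, x, y", path))
  df
}

#' Write a synthetic cohort's genotypes as a haploid VCF
#'
#' One record per site on contig `synth1` (1-based positions equal to site
#' indices), haploid `GT` fields (`0` or `1`), and the generating selection
#' class and coefficient in `INFO` (`SCLASS`, `SCOEF`) when annotations are
#' present. The model tracks haploid carriers, not diploid genotypes, so
#' the VCF is haploid by design.
#'
#' @param cht A [cohort()] object.
#' @param path Output file path (plain text).
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(cht, path) {
  stopifnot(inherits(cht, "cohort"))
  g <- cht$genotypes
  M <- nrow(g)
  if (M == 0L) stop("refusing to write a cohort with no sites")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=spatsfs %s", pkg_version()),
    "##contig=<ID=synth1>",
    "##INFO=<ID=SCLASS,Number=1,Type=String,Description=\"Selection class used to generate the site\">",
    "##INFO=<ID=SCOEF,Number=1,Type=Float,Description=\"Selection coefficient used to generate the site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cht$ids), collapse = "\t")), con)
  ann <- cht$annotations
  for (i in seq_len(M)) {
    gt <- rep("0", ncol(g))
    carriers <- which(g[i, ] != 0)
    gt[carriers] <- "1"
    info <- if (!is.null(ann))
      sprintf("SCLASS=%s;SCOEF=%g", ann$class[i], ann$s[i]) else "."
    writeLines(paste(c("synth1", i, sprintf("site%d", i), "A", "T", ".",
                       "PASS", info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a haploid cohort VCF
#'
#' Parses a VCF written by [write_cohort_vcf()] (requires the `vcfR`
#' package) and returns the genotype matrix with any selection-class
#' annotations.
#'
#' @param path VCF file path.
#' @return A list with `genotypes` (sites x individuals 0/1 sparse matrix),
#'   `ids`, and `annotations` (`NULL` if the INFO fields are absent).
#' @export
read_cohort_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  num <- matrix(as.numeric(gt == "1"), nrow = nrow(gt))
  info <- vcfR::getINFO(v)
  ann <- NULL
  if (any(grepl("SCLASS=", info))) {
    ann <- data.frame(
      site = seq_len(nrow(num)),
      class = sub(".*SCLASS=([^;]+).*", "\\1", info),
      s = as.numeric(sub(".*SCOEF=([^;]+).*", "\\1", info)))
  }
  list(genotypes = Matrix::Matrix(num, sparse = TRUE),
       ids = colnames(gt), annotations = ann)
}

#' Parse a flat key = value configuration file
#'
#' Reads the flat `key = value` configuration schema used by the
#' command-line interface (one assignment per line, `#` comments, values
#' coerced to numeric/logical where unambiguous). Keys not in `allowed`
#' are rejected, and `overrides` (e.g. command-line flags) take precedence
#' over file values.
#'
#' @param path Config file path, or `NULL` to use overrides only.
#' @param allowed Character vector of permitted keys (`NULL` = accept all).
#' @param overrides Named list of values that win over the file.
#' @return Named list of configuration values.
#' @export
parse_config <- function(path = NULL, allowed = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
      ln <- sub("#.*$", "", lines[i])
      ln <- trimws(ln)
      if (ln == "") next
      kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3L)
        stop(sprintf("%s: line %d is not a key = value assignment: '%s'",
                     path, i, lines[i]))
      cfg[[kv[2]]] <- coerce_scalar(kv[3])
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  if (!is.null(allowed)) {
    bad <- setdiff(names(cfg), allowed)
    if (length(bad))
      stop(sprintf("unknown configuration key(s): %s",
                   paste(bad, collapse = ", ")))
  }
  cfg
}
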