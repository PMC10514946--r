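#' Genotype container: sites, samples and a diploid dosage matrix
#'
#' A `geno` object bundles a per-site table with a sites-by-samples matrix of
#' alternate-allele dosages. Dosages are integers in `{0, 1, 2}` counting
#' copies of the first alternate allele; missing genotypes are `NA`. All
#' windowed statistics, the divergence scan, PCA and the simulator operate on
#' this container.
#'
#' @param sites A data frame with one row per variant site and at least the
#'   columns `chrom` (character) and `pos` (1-based position in bp). Optional
#'   columns `id`, `ref`, `alt` (comma-separated alternate alleles),
#'   `is_indel`, `is_multiallelic` and `is_mapped` are filled with defaults
#'   when absent (`ref = "A"`, `alt = "T"`, flags recomputed from the alleles).
#' @param dosage An integer matrix, sites in rows and samples in columns, with
#'   entries in `{0, 1, 2}` or `NA`.
#' @param samples Character vector of sample identifiers, one per matrix
#'   column.
#'
#' @return An object of class `geno`: a list with elements `sites` (a tibble),
#'   `dosage` and `samples`.
#' @export
#' @examples
#' g <- geno(
#'   sites = data.frame(chrom = "Vu01", pos = c(100L, 200L)),
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   samples = c("s1", "s2")
#' )
#' n_sites(g)
geno <- function(sites, dosage, samples) {
  sites <- tibble::as_tibble(sites)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    stop("`sites` needs at least columns `chrom` and `pos`", call. = FALSE)
  }
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = nrow(sites))
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites) || ncol(dosage) != length(samples)) {
    stop("dosage matrix dimensions do not match sites x samples", call. = FALSE)
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be in {0, 1, 2} or NA", call. = FALSE)
  }
  if (any(sites$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicated sample ids", call. = FALSE)
  if (is.null(sites[["id"]])) sites$id <- NA_character_
  if (is.null(sites[["ref"]])) sites$ref <- "A"
  if (is.null(sites[["alt"]])) sites$alt <- "T"
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  if (is.null(sites[["is_indel"]])) {
    sites$is_indel <- nchar(sites$ref) > 1L |
      vapply(alts, function(a) any(nchar(a) != 1L), logical(1))
  }
  if (is.null(sites[["is_multiallelic"]])) {
    sites$is_multiallelic <- lengths(alts) > 1L
  }
  if (is.null(sites[["is_mapped"]])) sites$is_mapped <- TRUE
  colnames(dosage) <- samples
  structure(list(sites = sites, dosage = dosage, samples = samples),
            class = "geno")
}

#' @rdname geno
#' @param x,g A `geno` object.
#' @export
n_sites <- function(g) nrow(g$sites)

#' @rdname geno
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname geno
#' @param i,j Site (row) and sample (column) indices.
#' @param ... Ignored.
#' @export
`[.geno` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  if (is.character(j)) j <- match(j, x$samples)
  geno(x$sites[i, , drop = FALSE],
       x$dosage[i, j, drop = FALSE],
       x$samples[j])
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d sites x %d samples (%.1f%% missing)\n",
              n_sites(x), n_samples(x),
              100 * mean(is.na(x$dosage))))
  chroms <- unique(x$sites$chrom)
  cat("  contigs:", paste(utils::head(chroms, 6), collapse = ", "),
      if (length(chroms) > 6) sprintf("... (%d)", length(chroms)) else "", "\n")
  invisible(x)
}

#' Missing-genotype fraction and alternate-allele frequency per site
#'
#' @param g A [geno()] object.
#' @return A tibble with columns `chrom`, `pos`, `n_called`, `missing_frac`,
#'   `alt_freq` and `maf` (minor allele frequency over non-missing alleles).
#' @export
site_summary <- function(g) {
  n_called <- rowSums(!is.na(g$dosage))
  ac <- rowSums(g$dosage, na.rm = TRUE)
  p <- ifelse(n_called > 0, ac / (2 * n_called), NA_real_)
  tibble::tibble(
    chrom = g$sites$chrom, pos = g$sites$pos,
    n_called = n_called,
    missing_frac = 1 - n_called / n_samples(g),
    alt_freq = p,
    maf = pmin(p, 1 - p)
  )
}
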