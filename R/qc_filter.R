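#' Filter SNPs by indel status, allele structure, missingness and MAF
#'
#' Applies the standard GBS retention rules: drop indels, drop multiallelic
#' sites and sites monomorphic for a non-reference allele, drop sites with a
#' missing-genotype fraction strictly above `max_missing`, and drop sites with
#' minor allele frequency (over non-missing alleles) strictly below `min_maf`.
#' Each removed site is attributed to the *first* rule that triggers, in the
#' order indel, allele structure, missingness, MAF, so the report counts
#' partition the input exactly.
#'
#' Thresholds are strict in the conventional reading: a site with exactly
#' `max_missing` missingness or exactly `min_maf` frequency is kept.
#'
#' @param g A [geno()] object.
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @param min_maf Minimum tolerated minor allele frequency (default 0.05).
#' @param drop_indels Drop sites whose REF or any ALT allele is longer than
#'   one base.
#' @param biallelic_snps_only Drop multiallelic sites.
#' @param drop_nonref_monomorphic Drop sites at which every called allele is
#'   the (first) alternate allele.
#' @return A list of class `divscan_filter` with elements `geno` (the filtered
#'   container) and `report`, a one-row tibble with the counts
#'   `n_raw`, `n_removed_indel`, `n_removed_multiallelic_or_nonref`,
#'   `n_removed_missing`, `n_removed_maf`, `n_retained` and
#'   `removed_fraction` (percent).
#' @export
#' @examples
#' g <- geno(data.frame(chrom = "Vu01", pos = c(10L, 20L), ref = c("A", "A"),
#'                      alt = c("T", "AT")),
#'           matrix(c(0L, 1L, 1L, 2L), 2, 2), c("s1", "s2"))
#' filter_sites(g)$report
filter_sites <- function(g, max_missing = 0.10, min_maf = 0.05,
                         drop_indels = TRUE, biallelic_snps_only = TRUE,
                         drop_nonref_monomorphic = TRUE) {
  stopifnot(inherits(g, "geno"),
            max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  if (n_sites(g) == 0) stop("empty genotype matrix", call. = FALSE)
  ss <- site_summary(g)
  is_indel <- g$sites$is_indel
  is_bad_allele <- (if (biallelic_snps_only) g$sites$is_multiallelic else FALSE) |
    (if (drop_nonref_monomorphic) !is.na(ss$alt_freq) & ss$alt_freq >= 1 else FALSE)
  too_missing <- ss$missing_frac > max_missing
  low_maf <- is.na(ss$maf) | ss$maf < min_maf

  reason <- rep("retained", n_sites(g))
  reason[low_maf] <- "maf"
  reason[too_missing] <- "missing"
  reason[is_bad_allele] <- "allele"
  if (drop_indels) reason[is_indel] <- "indel"

  keep <- reason == "retained"
  report <- tibble::tibble(
    n_raw = n_sites(g),
    n_removed_indel = sum(reason == "indel"),
    n_removed_multiallelic_or_nonref = sum(reason == "allele"),
    n_removed_missing = sum(reason == "missing"),
    n_removed_maf = sum(reason == "maf"),
    n_retained = sum(keep),
    removed_fraction = removed_fraction(n_sites(g), sum(keep))
  )
  if (!any(keep)) warning("all sites removed by the filter", call. = FALSE)
  structure(list(geno = g[keep, ], report = report), class = "divscan_filter")
}

#' @export
print.divscan_filter <- function(x, ...) {
  r <- x$report
  cat(sprintf("<divscan_filter> %d raw -> %d retained (%.1f%% removed)\n",
              r$n_raw, r$n_retained, r$removed_fraction))
  cat(sprintf("  indel %d | multiallelic/non-ref %d | missing %d | MAF %d\n",
              r$n_removed_indel, r$n_removed_multiallelic_or_nonref,
              r$n_removed_missing, r$n_removed_maf))
  invisible(x)
}

#' Percentage of sites removed, to one decimal
#'
#' `100 * (n_raw - n_retained) / n_raw`, rounded to one decimal place — the
#' form in which GBS filter attrition is conventionally reported.
#'
#' @param n_raw,n_retained Site counts before and after filtering.
#' @return A single number (percent).
#' @export
#' @examples
#' removed_fraction(63947, 11083)
removed_fraction <- function(n_raw, n_retained) {
  stopifnot(n_raw > 0, n_retained >= 0, n_retained <= n_raw)
  round(100 * (n_raw - n_retained) / n_raw, 1)
}

#' Per-chromosome SNP density table
#'
#' Builds the classical marker-density summary: one row per assembled
#' chromosome with SNP count, size in Mbp and density in SNP/Mbp (2 decimals),
#' one pooled `Unmapped` row for all other contigs, and a `Total` row. The
#' mean and sample (n-1) standard deviation of the mapped-chromosome densities
#' are attached as columns of the returned summary attributes.
#'
#' @param sites A tibble with a `chrom` column (e.g. `g$sites`), or a `geno`.
#' @param chrom_sizes Tibble from [read_chrom_sizes()]; lengths in bp.
#' @param mapped_chroms Character vector of assembled chromosome names; other
#'   contigs are pooled into the unmapped row.
#' @return A tibble with columns `chrom`, `n_snps`, `size_mbp`, `density`
#'   (SNP/Mbp, 2 dp). Attributes: `mapped_density_mean`, `mapped_density_sd`
#'   (both 2 dp), `sd_defined` (FALSE when fewer than 2 mapped chromosomes),
#'   `unmapped_share` (percent of SNPs on unmapped contigs, 1 dp).
#' @export
density_summary <- function(sites, chrom_sizes, mapped_chroms) {
  if (inherits(sites, "geno")) sites <- sites$sites
  missing_chr <- setdiff(unique(sites$chrom), chrom_sizes$chrom)
  if (length(missing_chr)) {
    stop("site(s) on contig(s) absent from chromosome sizes: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(sites$chrom, levels = chrom_sizes$chrom))
  mapped <- chrom_sizes$chrom %in% mapped_chroms
  rows <- tibble::tibble(
    chrom = chrom_sizes$chrom[mapped],
    n_snps = as.integer(counts[mapped]),
    size_mbp = chrom_sizes$length[mapped] / 1e6
  )
  unmapped_n <- sum(counts[!mapped])
  unmapped_size <- sum(chrom_sizes$length[!mapped]) / 1e6
  if (any(!mapped)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      chrom = "Unmapped", n_snps = as.integer(unmapped_n), size_mbp = unmapped_size))
  }
  total <- tibble::tibble(chrom = "Total",
                          n_snps = sum(rows$n_snps),
                          size_mbp = sum(rows$size_mbp))
  out <- dplyr::bind_rows(rows, total)
  out$density <- round(out$n_snps / out$size_mbp, 2)
  dens_mapped <- out$density[!out$chrom %in% c("Unmapped", "Total")]
  sd_defined <- length(dens_mapped) >= 2
  attr(out, "mapped_density_mean") <- round(mean(dens_mapped), 2)
  attr(out, "mapped_density_sd") <- if (sd_defined) round(stats::sd(dens_mapped), 2) else 0
  attr(out, "sd_defined") <- sd_defined
  attr(out, "unmapped_share") <- round(100 * unmapped_n / max(1, sum(counts)), 1)
  out
}
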