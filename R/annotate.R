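# Overlap of peak flanking regions with gene/QTL intervals. All coordinates
# are 1-based inclusive; overlap means >= 1 shared bp (closed intervals).

# indices of `ivs` rows intersecting [start, end] on `chrom`
.overlap_idx <- function(chrom, start, end, ivs) {
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start, end),
    IRanges::IRanges(ivs$start, ivs$end))
  j <- S4Vectors::subjectHits(hits)
  j[ivs$chrom[j] == chrom]
}

#' Genes intersecting a peak's flanking region
#'
#' Returns all gene intervals with at least one bp of intersection with the
#' flanking interval `[flank_start, flank_end]` of each peak (closed
#' intervals: a gene starting exactly at `flank_end` overlaps by 1 bp),
#' sorted by start.
#'
#' @param peaks Tibble from [merge_peaks()] (needs `chrom`, `flank_start`,
#'   `flank_end`).
#' @param genes Interval tibble from [read_intervals()].
#' @return A tibble with one row per (peak, gene) overlap: peak coordinates
#'   plus `gene`, `gene_start`, `gene_end`.
#' @export
genes_in_flank <- function(peaks, genes) {
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    j <- .overlap_idx(peaks$chrom[i], peaks$flank_start[i],
                      peaks$flank_end[i], genes)
    j <- j[order(genes$start[j])]
    if (!length(j)) return(NULL)
    tibble::tibble(chrom = peaks$chrom[i], peak_start = peaks$start[i],
                   peak_end = peaks$end[i],
                   gene = genes$name[j],
                   gene_start = genes$start[j], gene_end = genes$end[j])
  })
}

#' QTL intervals overlapping a peak's flanking region
#'
#' @param peaks Tibble from [merge_peaks()].
#' @param qtls Interval tibble from [read_intervals()] with a `trait` column.
#' @return A tibble with one row per (peak, QTL) overlap, trait propagated.
#' @export
qtl_overlap <- function(peaks, qtls) {
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    j <- .overlap_idx(peaks$chrom[i], peaks$flank_start[i],
                      peaks$flank_end[i], qtls)
    if (!length(j)) return(NULL)
    tibble::tibble(chrom = peaks$chrom[i], peak_start = peaks$start[i],
                   peak_end = peaks$end[i],
                   qtl = qtls$name[j], trait = qtls$trait[j])
  })
}

#' Annotate divergence peaks with gene counts and QTL traits
#'
#' Produces the summary table of divergence peaks: peak coordinates, length,
#' mean F_ST, the flanking interval, the number (and names) of genes in the
#' flank, and the traits of any known QTL the flank overlaps. Gene search is
#' in the flanking region, not the narrow peak.
#'
#' @param peaks Tibble from [merge_peaks()] (a `pair` column, if present, is
#'   carried through).
#' @param genes,qtls Optional interval tibbles from [read_intervals()].
#' @return A tibble with one row per peak: `chrom`, `start`, `end`, `length`,
#'   `mean_fst`, `flank_start`, `flank_end`, `gene_count`, `genes`,
#'   `qtl_traits` (comma-separated; empty string when none).
#' @export
annotate_peaks <- function(peaks, genes = NULL, qtls = NULL) {
  base_cols <- intersect(c("pair", "chrom", "start", "end", "length",
                           "mean_fst", "flank_start", "flank_end"),
                         names(peaks))
  out <- peaks[, base_cols, drop = FALSE]
  out$gene_count <- 0L
  out$genes <- ""
  out$qtl_traits <- ""
  for (i in seq_len(nrow(out))) {
    if (!is.null(genes) && nrow(genes)) {
      j <- .overlap_idx(peaks$chrom[i], peaks$flank_start[i],
                        peaks$flank_end[i], genes)
      j <- j[order(genes$start[j])]
      out$gene_count[i] <- length(j)
      out$genes[i] <- paste(genes$name[j], collapse = ",")
    }
    if (!is.null(qtls) && nrow(qtls)) {
      j <- .overlap_idx(peaks$chrom[i], peaks$flank_start[i],
                        peaks$flank_end[i], qtls)
      out$qtl_traits[i] <- paste(unique(stats::na.omit(qtls$trait[j])),
                                 collapse = ",")
    }
  }
  tibble::as_tibble(out)
}
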