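#' Permutation-calibrated genome-wide outlier threshold for windowed F_ST
#'
#' Builds an empirical null for the windowed F_ST statistic and returns its
#' `1 - alpha` quantile as the outlier threshold, pooling all defined window
#' values across permutations into a single genome-wide null (one threshold
#' per comparison).
#'
#' Two null schemes are available. `"site"` (default) permutes the per-site
#' variance-component records across SNP positions genome-wide and recomputes
#' the window statistic on the same grid: the marginal distribution of
#' per-site F_ST is preserved exactly and only its arrangement along the
#' genome is destroyed, so a window is an outlier when its sites are more
#' concordantly divergent than a random draw of the same number of sites from
#' the whole genome. `"label"` reshuffles population labels among the samples
#' of the compared pair (sizes preserved) and recomputes components and window
#' statistics; it nulls *all* divergence, including genome-wide background
#' structure, and is appropriate only when the background is expected to be
#' panmictic.
#'
#' @param g A [geno()] object.
#' @param pop_map Tibble with columns `sample`, `population`.
#' @param pair Two population labels.
#' @param windows Window grid from [make_windows()].
#' @param alpha Upper-tail probability (default 0.001).
#' @param n_permutations Number of permutations (default 1000). A warning is
#'   given when `n_permutations * n_windows` poorly resolves `alpha`.
#' @param seed Integer seed; the threshold is reproducible given the seed.
#' @param mode Window statistic to threshold: `"weighted"` (default; the
#'   ratio-of-sums combination) or `"mean"`.
#' @param scheme `"site"` or `"label"` (see Details).
#' @param min_sites Minimum usable sites for a window to enter the null pool
#'   (and, downstream, to be callable as an outlier). Windows with one or two
#'   SNPs carry unstable F_ST estimates and dominate the extreme tail of the
#'   pooled null; the default of 3 excludes them symmetrically from the
#'   observed and permuted sets (under the site scheme the per-window site
#'   count is permutation-invariant, so eligibility is identical on both
#'   sides and calibration is unaffected).
#' @return A one-row tibble of class `divscan_threshold`: `pop_a`, `pop_b`,
#'   `alpha`, `n_permutations`, `scheme`, `mode`, `min_sites`, `threshold`,
#'   `seed`.
#' @export
permutation_threshold <- function(g, pop_map, pair, windows,
                                  alpha = 0.001, n_permutations = 1000,
                                  seed = 1L,
                                  mode = c("weighted", "mean"),
                                  scheme = c("site", "label"),
                                  min_sites = 3) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  stopifnot(alpha > 0, alpha <= 1, n_permutations >= 1)
  if (n_permutations < 1 / alpha / max(1, nrow(windows))) {
    warning("n_permutations is small for alpha = ", alpha,
            "; threshold will be poorly resolved", call. = FALSE)
  }
  comp <- wc_components(g, pop_map, pair)
  map <- .window_site_map(comp$chrom, comp$pos, windows)
  pops <- population_of(pop_map, g$samples)
  i1 <- which(pops == pair[1])
  i2 <- which(pops == pair[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("both populations need >= 2 samples for permutation", call. = FALSE)
  }
  nsite <- nrow(comp)
  win_stat <- function(a, den, ratio, usable) {
    s <- .window_sums(map, list(sa = a, sden = den, sratio = ratio), usable)
    v <- if (mode == "weighted") {
      ifelse(s$n_sites > 0 & s$sden > 0, s$sa / s$sden, NA_real_)
    } else {
      ifelse(s$n_sites > 0, s$sratio / s$n_sites, NA_real_)
    }
    v[s$n_sites < min_sites] <- NA_real_
    v
  }
  pool <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_permutations), function(b) {
      if (scheme == "site") {
        o <- sample.int(nsite)
        v <- win_stat(comp$a[o], (comp$a + comp$b + comp$c)[o],
                      comp$fst[o], comp$usable[o])
      } else {
        shuffled <- sample(c(i1, i2))
        j1 <- shuffled[seq_along(i1)]
        j2 <- shuffled[-seq_along(i1)]
        c1 <- .pop_counts(g$dosage, j1)
        c2 <- .pop_counts(g$dosage, j2)
        w <- .wc_from_counts(c1$n, c1$ac, c1$het, c2$n, c2$ac, c2$het)
        v <- win_stat(w$a, w$den, w$fst, w$usable)
      }
      v[!is.na(v)]
    })
  })
  thr <- stats::quantile(unlist(pool), 1 - alpha, names = FALSE, type = 7)
  structure(
    tibble::tibble(pop_a = pair[1], pop_b = pair[2], alpha = alpha,
                   n_permutations = as.integer(n_permutations),
                   scheme = scheme, mode = mode,
                   min_sites = as.integer(min_sites),
                   threshold = thr, seed = as.integer(seed)),
    class = c("divscan_threshold", "tbl_df", "tbl", "data.frame"))
}

#' Flag outlier windows above a threshold
#'
#' A window is flagged iff its `fst` value strictly exceeds the threshold and
#' it contains at least `min_sites` usable sites; ties and undefined windows
#' are never flagged. `min_sites` defaults to the value recorded in a
#' `divscan_threshold`, else 1.
#'
#' @param window_stats Tibble from [windowed_fst()] (needs `fst`, `n_sites`).
#' @param threshold A number, or a `divscan_threshold` row.
#' @param min_sites Minimum usable sites for eligibility; see
#'   [permutation_threshold()].
#' @return The flagged subset of `window_stats`, with an `outlier` column.
#' @export
call_outlier_windows <- function(window_stats, threshold, min_sites = NULL) {
  if (inherits(threshold, "data.frame")) {
    if (is.null(min_sites) && "min_sites" %in% names(threshold)) {
      min_sites <- threshold$min_sites
    }
    threshold <- threshold$threshold
  }
  if (is.null(min_sites)) min_sites <- 1
  stopifnot(is.finite(threshold))
  out <- window_stats[!is.na(window_stats$fst) &
                        window_stats$n_sites >= min_sites &
                        window_stats$fst > threshold, , drop = FALSE]
  out$outlier <- rep(TRUE, nrow(out))
  out
}

#' Merge consecutive outlier windows into divergence peaks
#'
#' Maximal runs of grid-consecutive flagged windows (adjacent starts differing
#' by exactly `step`) are merged into one peak. With
#' `boundary_mode = "snp"` the peak is delimited by the first and last SNP
#' inside the run's union span — peaks are then as narrow as the marker
#' clusters that drive them; with `"window_midpoint"` the peak runs from the
#' midpoint of the first window to the midpoint of the last. The flanking
#' interval is anchored at the peak start: `flank = [start - 50kb, start +
#' 50kb]`, clipped at chromosome bounds (and flagged) when sizes are given.
#'
#' @param flagged Tibble of flagged windows from [call_outlier_windows()].
#' @param sites Tibble with `chrom`, `pos` of the SNPs the windows were
#'   computed from (used for `"snp"` boundaries).
#' @param step Grid step in bp (default 10,000).
#' @param boundary_mode `"snp"` (default) or `"window_midpoint"`.
#' @param flank_radius Half-width of the flanking interval (default 50,000).
#' @param chrom_sizes Optional tibble (`chrom`, `length`) to clip flanks.
#' @return A tibble with one row per peak: `chrom`, `start`, `end`, `length`,
#'   `n_windows`, `mean_fst` (mean of member-window `fst` values),
#'   `flank_start`, `flank_end`, `flank_clipped`.
#' @export
merge_peaks <- function(flagged, sites, step = 10000,
                        boundary_mode = c("snp", "window_midpoint"),
                        flank_radius = 50000, chrom_sizes = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), length = numeric(),
                          n_windows = integer(), mean_fst = numeric(),
                          flank_start = numeric(), flank_end = numeric(),
                          flank_clipped = logical())
  if (nrow(flagged) == 0) return(empty)
  flagged <- dplyr::arrange(flagged, .data$chrom, .data$start)
  peaks <- flagged |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$start) != step))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(span_start = min(.data$start), span_end = max(.data$end),
                     first_mid = floor((min(.data$start) + min(.data$end)) / 2),
                     last_mid = floor((max(.data$start) + max(.data$end)) / 2),
                     n_windows = dplyr::n(),
                     mean_fst = mean(.data$fst), .groups = "drop")
  if (boundary_mode == "snp") {
    bounds <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
      p <- sites$pos[sites$chrom == peaks$chrom[i] &
                       sites$pos >= peaks$span_start[i] &
                       sites$pos <= peaks$span_end[i]]
      if (!length(p)) {
        stop("no SNP inside outlier run on ", peaks$chrom[i], call. = FALSE)
      }
      tibble::tibble(start = as.numeric(min(p)), end = as.numeric(max(p)))
    })
  } else {
    bounds <- tibble::tibble(start = as.numeric(peaks$first_mid),
                             end = as.numeric(peaks$last_mid))
  }
  out <- tibble::tibble(
    chrom = peaks$chrom,
    start = bounds$start, end = bounds$end,
    length = bounds$end - bounds$start,
    n_windows = as.integer(peaks$n_windows),
    mean_fst = peaks$mean_fst,
    flank_start = bounds$start - flank_radius,
    flank_end = bounds$start + flank_radius
  )
  out$flank_clipped <- FALSE
  if (!is.null(chrom_sizes)) {
    L <- chrom_sizes$length[match(out$chrom, chrom_sizes$chrom)]
    clip <- out$flank_start < 1 | (!is.na(L) & out$flank_end > L)
    out$flank_start <- pmax(out$flank_start, 1)
    out$flank_end <- ifelse(is.na(L), out$flank_end, pmin(out$flank_end, L))
    out$flank_clipped <- clip
  } else {
    clip <- out$flank_start < 1
    out$flank_start <- pmax(out$flank_start, 1)
    out$flank_clipped <- clip
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Scan all population pairs for divergence peaks
#'
#' For each unordered pair of the given populations: windowed Weir-Cockerham
#' F_ST on the grid, a permutation-calibrated genome-wide threshold at
#' `alpha`, outlier windows, and merged peaks. An empty peak table for a pair
#' is a valid outcome.
#'
#' @inheritParams permutation_threshold
#' @param populations Character vector (>= 2) of population labels to compare
#'   pairwise.
#' @param size,step Window size and step in bp.
#' @param boundary_mode Passed to [merge_peaks()].
#' @param chrom_sizes Tibble (`chrom`, `length`) for the grid and flank
#'   clipping.
#' @return An object of class `divscan_scan`: a list with `windows`,
#'   `thresholds`, `peaks` (tibbles; `windows` and `peaks` carry a `pair`
#'   column) and `params`.
#' @export
scan_divergence <- function(g, pop_map, populations, chrom_sizes,
                            size = 100000, step = 10000,
                            alpha = 0.001, n_permutations = 1000, seed = 1L,
                            mode = c("weighted", "mean"),
                            scheme = c("site", "label"),
                            boundary_mode = c("snp", "window_midpoint"),
                            min_sites = 3) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(length(populations) >= 2)
  windows <- make_windows(chrom_sizes, size = size, step = step)
  prs <- utils::combn(populations, 2, simplify = FALSE)
  seeds <- as.integer(seed) + seq_along(prs) - 1L
  res <- purrr::map2(prs, seeds, function(pr, sd) {
    comp <- wc_components(g, pop_map, pr)
    ws <- windowed_fst(comp, windows,
                       mode = if (mode == "weighted") "weighted" else "mean")
    thr <- permutation_threshold(g, pop_map, pr, windows, alpha = alpha,
                                 n_permutations = n_permutations, seed = sd,
                                 mode = mode, scheme = scheme,
                                 min_sites = min_sites)
    fl <- call_outlier_windows(ws, thr)
    pk <- merge_peaks(fl, g$sites, step = step, boundary_mode = boundary_mode,
                      chrom_sizes = chrom_sizes)
    pair_lab <- paste(pr, collapse = "-")
    ws$pair <- pair_lab
    pk$pair <- pair_lab
    list(windows = ws, threshold = thr, peaks = pk)
  })
  structure(list(
    windows = dplyr::bind_rows(purrr::map(res, "windows")),
    thresholds = dplyr::bind_rows(purrr::map(res, "threshold")),
    peaks = dplyr::bind_rows(purrr::map(res, "peaks")),
    params = list(size = size, step = step, alpha = alpha,
                  n_permutations = n_permutations, seed = as.integer(seed),
                  mode = mode, scheme = scheme, boundary_mode = boundary_mode,
                  min_sites = min_sites, populations = populations)
  ), class = "divscan_scan")
}

#' @export
print.divscan_scan <- function(x, ...) {
  cat(sprintf("<divscan_scan> %d pair(s), alpha = %g, %d permutations (%s/%s)\n",
              nrow(x$thresholds), x$params$alpha, x$params$n_permutations,
              x$params$scheme, x$params$mode))
  for (i in seq_len(nrow(x$thresholds))) {
    pr <- paste(x$thresholds$pop_a[i], x$thresholds$pop_b[i], sep = "-")
    cat(sprintf("  %-35s thr = %.3f, %d peak(s)\n", pr,
                x$thresholds$threshold[i], sum(x$peaks$pair == pr)))
  }
  invisible(x)
}

#' Tidy a divergence scan into its peak table
#'
#' @param x A `divscan_scan`.
#' @param ... Ignored.
#' @return The peaks tibble (one row per divergence peak, all pairs).
#' @export
tidy.divscan_scan <- function(x, ...) x$peaks

#' One-row-per-comparison summary of a divergence scan
#'
#' @param x A `divscan_scan`.
#' @param ... Ignored.
#' @return A tibble with pair, threshold, window and peak counts.
#' @export
glance.divscan_scan <- function(x, ...) {
  thr <- x$thresholds
  thr$pair <- paste(thr$pop_a, thr$pop_b, sep = "-")
  dplyr::bind_cols(
    thr[, c("pair", "alpha", "threshold", "n_permutations", "scheme", "mode")],
    tibble::tibble(
      n_windows_defined = vapply(thr$pair, function(p)
        sum(!is.na(x$windows$fst[x$windows$pair == p])), integer(1)),
      n_outlier_windows = vapply(thr$pair, function(p)
        sum(x$peaks$n_windows[x$peaks$pair == p]), integer(1)),
      n_peaks = vapply(thr$pair, function(p)
        sum(x$peaks$pair == p), integer(1))
    )
  )
}
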