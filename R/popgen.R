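#' Sliding-window grid over a genome
#'
#' Windows of `size` bp advance by `step` bp along each chromosome; the last
#' windows are truncated at the chromosome end. A chromosome shorter than
#' `size` yields a single truncated window covering it entirely. With
#' `step = size` the grid is a non-overlapping tiling.
#'
#' @param chrom_sizes Tibble from [read_chrom_sizes()] (`chrom`, `length`).
#' @param size Window size in bp (default 100,000).
#' @param step Step between window starts in bp (default 10,000).
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
#' @examples
#' make_windows(tibble::tibble(chrom = "c1", length = 120000))
make_windows <- function(chrom_sizes, size = 100000, step = 10000) {
  stopifnot(size >= step, step >= 1)
  purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    L <- chrom_sizes$length[i]
    starts <- if (L < size) 1 else seq(1, L - step + 1, by = step)
    tibble::tibble(chrom = chrom_sizes$chrom[i],
                   start = starts,
                   end = pmin(starts + size - 1, L))
  })
}

# Per-population per-site counts from a dosage matrix: non-missing sample
# count, alt allele count, het count. Matrix products keep this O(sites).
.pop_counts <- function(dos, idx) {
  sub <- dos[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  list(n = n,
       ac = rowSums(sub, na.rm = TRUE),
       het = rowSums(sub == 1L, na.rm = TRUE))
}

# Weir & Cockerham (1984) two-population diploid variance components from
# per-population counts. Returns a, b, c per site plus usability flags.
# Sites monomorphic across both populations get a = b = c = 0.
.wc_from_counts <- function(n1, ac1, het1, n2, ac2, het2) {
  ok <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(n1 > 0, ac1 / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, ac2 / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, het1 / n1, NA_real_)
  h2 <- ifelse(n2 > 0, het2 / n2, NA_real_)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- !is.na(pbar) & (pbar <= 0 | pbar >= 1)
  a[mono | !ok] <- 0
  b[mono | !ok] <- 0
  cc[mono | !ok] <- 0
  den <- a + b + cc
  usable <- ok & !mono & den > 0
  list(a = a, b = b, c = cc, den = den,
       fst = ifelse(usable, a / den, NA_real_),
       usable = usable, n1 = n1, n2 = n2)
}

#' Per-site Weir-Cockerham variance components for a population pair
#'
#' Computes the diploid two-population estimator of the fixation index: the
#' among-population (`a`), among-individual-within-population (`b`) and
#' within-individual (`c`) variance components, using observed heterozygosity
#' and per-site non-missing sample sizes. The per-site F_ST estimate is
#' `a / (a + b + c)`; negative estimates are retained. A site contributes only
#' when both populations have at least two called genotypes there; sites
#' monomorphic across both populations get zero components and are flagged
#' unusable.
#'
#' @param g A [geno()] object.
#' @param pop_map Tibble with columns `sample`, `population`.
#' @param pair Character vector of two population labels.
#' @return A tibble with one row per site: `chrom`, `pos`, `a`, `b`, `c`,
#'   `n_1`, `n_2`, `fst`, `usable`.
#' @export
wc_components <- function(g, pop_map, pair) {
  stopifnot(inherits(g, "geno"), length(pair) == 2)
  pops <- population_of(pop_map, g$samples)
  i1 <- which(pops == pair[1])
  i2 <- which(pops == pair[2])
  if (!length(i1) || !length(i2)) {
    stop("population(s) not present among samples: ",
         paste(pair[!(pair %in% pops)], collapse = ", "), call. = FALSE)
  }
  c1 <- .pop_counts(g$dosage, i1)
  c2 <- .pop_counts(g$dosage, i2)
  w <- .wc_from_counts(c1$n, c1$ac, c1$het, c2$n, c2$ac, c2$het)
  if (!any(w$n1 >= 2) || !any(w$n2 >= 2)) {
    stop("a population has fewer than 2 called genotypes at every site",
         call. = FALSE)
  }
  tibble::tibble(chrom = g$sites$chrom, pos = g$sites$pos,
                 a = w$a, b = w$b, c = w$c,
                 n_1 = w$n1, n_2 = w$n2,
                 fst = w$fst, usable = w$usable)
}

# Map each window to the index range of (position-sorted) sites it contains.
# Returns per-chromosome closures reused across permutations.
.window_site_map <- function(site_chrom, site_pos, windows) {
  chroms <- unique(windows$chrom)
  lapply(stats::setNames(chroms, chroms), function(ch) {
    sel <- which(site_chrom == ch)
    pos <- site_pos[sel]
    if (is.unsorted(pos)) {
      o <- order(pos)
      sel <- sel[o]
      pos <- pos[o]
    }
    w <- windows[windows$chrom == ch, ]
    list(sel = sel,
         lo = findInterval(w$start - 1, pos),
         hi = findInterval(w$end, pos),
         start = w$start, end = w$end)
  })
}

# Windowed sums of one or more per-site vectors via cumulative sums.
# vals: named list of numeric vectors aligned with sites; returns a tibble of
# windows with a `n_sites` count and one summed column per input vector.
.window_sums <- function(map, vals, usable) {
  purrr::map_dfr(names(map), function(ch) {
    mp <- map[[ch]]
    u <- usable[mp$sel]
    cn <- c(0, cumsum(as.numeric(u)))
    out <- tibble::tibble(chrom = ch, start = mp$start, end = mp$end,
                          n_sites = cn[mp$hi + 1] - cn[mp$lo + 1])
    for (nm in names(vals)) {
      v <- vals[[nm]][mp$sel]
      v[!u] <- 0
      cs <- c(0, cumsum(v))
      out[[nm]] <- cs[mp$hi + 1] - cs[mp$lo + 1]
    }
    out
  })
}

#' Windowed F_ST from per-site variance components
#'
#' Two window summaries are computed from the usable sites in each window:
#' `mean_fst`, the average of per-site ratios `a/(a+b+c)` (the "average
#' pairwise F_ST per window" convention; negative per-site values retained),
#' and `weighted_fst`, the ratio of sums `sum(a)/sum(a+b+c)`, which weights
#' sites by their information content and is the Weir-Cockerham recommended
#' multi-locus combination. The `fst` column duplicates the one selected by
#' `mode`. Windows with no usable site have `NA` statistics.
#'
#' @param components Tibble from [wc_components()].
#' @param windows Window grid from [make_windows()].
#' @param mode Which summary the `fst` column carries: `"mean"` (default) or
#'   `"weighted"`.
#' @return The window grid plus `n_sites`, `mean_fst`, `weighted_fst`, `fst`.
#' @export
windowed_fst <- function(components, windows, mode = c("mean", "weighted")) {
  mode <- match.arg(mode)
  map <- .window_site_map(components$chrom, components$pos, windows)
  ratio <- components$fst
  ratio[!components$usable] <- 0
  out <- .window_sums(map,
                      list(sum_ratio = ratio, sum_a = components$a,
                           sum_den = components$a + components$b + components$c),
                      components$usable)
  out$mean_fst <- ifelse(out$n_sites > 0, out$sum_ratio / out$n_sites, NA_real_)
  out$weighted_fst <- ifelse(out$n_sites > 0 & out$sum_den > 0,
                             out$sum_a / out$sum_den, NA_real_)
  out$fst <- if (mode == "mean") out$mean_fst else out$weighted_fst
  dplyr::select(out, "chrom", "start", "end", "n_sites",
                "mean_fst", "weighted_fst", "fst")
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity is the unbiased heterozygosity
#' `2 * n_alt * n_ref / (n * (n - 1))` over the `n` non-missing alleles in the
#' chosen sample subset; the window value is the sum of per-site diversities
#' divided by the window length in bp, so invariant positions dilute the
#' estimate as in genome-windowed diversity scans.
#'
#' @param g A [geno()] object.
#' @param windows Window grid from [make_windows()].
#' @param pop_map Optional population map; required when `pop_subset` names
#'   populations.
#' @param pop_subset Optional character vector of population labels; when
#'   `NULL` all samples are used.
#' @return The window grid plus `n_sites` (polymorphic sites used) and `pi`
#'   (per-bp diversity).
#' @export
windowed_pi <- function(g, windows, pop_map = NULL, pop_subset = NULL) {
  idx <- seq_len(n_samples(g))
  if (!is.null(pop_subset)) {
    if (is.null(pop_map)) stop("pop_subset needs pop_map", call. = FALSE)
    idx <- which(population_of(pop_map, g$samples) %in% pop_subset)
    if (!length(idx)) stop("empty population subset", call. = FALSE)
  }
  cc <- .pop_counts(g$dosage, idx)
  n_alleles <- 2 * cc$n
  site_pi <- ifelse(n_alleles >= 2,
                    2 * cc$ac * (n_alleles - cc$ac) /
                      (n_alleles * (n_alleles - 1)), 0)
  site_pi[is.na(site_pi)] <- 0
  map <- .window_site_map(g$sites$chrom, g$sites$pos, windows)
  out <- .window_sums(map, list(sum_pi = site_pi), usable = site_pi > 0)
  out$pi <- out$sum_pi / (out$end - out$start + 1)
  dplyr::select(out, "chrom", "start", "end", "n_sites", "pi")
}

#' Windowed linkage disequilibrium (mean r-squared)
#'
#' For every pair of sites inside a window, r-squared is the squared Pearson
#' correlation of genotype dosages across the samples called at both sites
#' (composite, phase-free LD). The window value is the mean over defined
#' pairs; a pair is skipped when either site has zero dosage variance in the
#' complete-case subset. Windows with fewer than `min_pairs` defined pairs
#' are `NA`.
#'
#' @param g A [geno()] object.
#' @param windows Window grid from [make_windows()].
#' @param min_pairs Minimum number of defined site pairs (default 1).
#' @return The window grid plus `n_pairs` and `mean_r2`.
#' @export
windowed_r2 <- function(g, windows, min_pairs = 1) {
  map <- .window_site_map(g$sites$chrom, g$sites$pos, windows)
  dos <- g$dosage
  purrr::map_dfr(names(map), function(ch) {
    mp <- map[[ch]]
    res <- vapply(seq_along(mp$start), function(k) {
      if (mp$hi[k] - mp$lo[k] < 2) return(c(NA_real_, 0))
      rows <- mp$sel[(mp$lo[k] + 1):mp$hi[k]]
      cm <- suppressWarnings(
        stats::cor(t(dos[rows, , drop = FALSE]), use = "pairwise.complete.obs"))
      vals <- cm[upper.tri(cm)]^2
      vals <- vals[!is.na(vals)]
      if (length(vals) < min_pairs) c(NA_real_, length(vals))
      else c(mean(vals), length(vals))
    }, numeric(2))
    tibble::tibble(chrom = ch, start = mp$start, end = mp$end,
                   n_pairs = as.integer(res[2, ]), mean_r2 = res[1, ])
  })
}
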