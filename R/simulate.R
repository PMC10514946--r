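#' Default chromosome sizes for the simulated cowpea-like genome
#'
#' Eleven assembled chromosomes plus one pooled unmapped contig, at the sizes
#' of the cowpea reference assembly (Mbp converted to bp).
#'
#' @return A tibble with columns `chrom`, `length`.
#' @export
default_chrom_sizes <- function() {
  tibble::tibble(
    chrom = c(sprintf("Vu%02d", 1:11), "contig_unmapped"),
    length = c(42.13, 33.91, 65.29, 42.73, 48.75, 34.46,
               40.88, 38.36, 43.93, 41.33, 41.68, 45.98) * 1e6
  )
}

#' Default planted divergence islands
#'
#' Twelve 250-kb regions at loci echoing the divergence peaks reported for
#' cultivated cowpea: nine differentiating the grain and vegetable
#' subspecies, three the vegetable and fodder subspecies. Each island names
#' the two populations whose allele frequencies are drawn at the island
#' `fst`; all other populations stay at the background divergence there.
#'
#' @param width Island width in bp (default 250,000).
#' @param fst Island divergence parameter (default 0.6).
#' @return A tibble with columns `chrom`, `start`, `end`, `pop_a`, `pop_b`,
#'   `fst`.
#' @export
default_islands <- function(width = 250000, fst = 0.6) {
  loci <- tibble::tribble(
    ~chrom, ~start, ~pop_a, ~pop_b,
    "Vu02", 24.50e6, "unguiculata", "sesquipedalis",
    "Vu03",  7.35e6, "unguiculata", "sesquipedalis",
    "Vu03", 13.55e6, "unguiculata", "sesquipedalis",
    "Vu03", 14.35e6, "unguiculata", "sesquipedalis",
    "Vu04",  2.85e6, "unguiculata", "sesquipedalis",
    "Vu06", 23.20e6, "unguiculata", "sesquipedalis",
    "Vu08", 33.03e6, "unguiculata", "sesquipedalis",
    "Vu10", 33.18e6, "unguiculata", "sesquipedalis",
    "Vu11", 23.85e6, "unguiculata", "sesquipedalis",
    "Vu03", 14.51e6, "sesquipedalis", "cylindrica",
    "Vu09", 15.45e6, "sesquipedalis", "cylindrica",
    "Vu09", 16.05e6, "sesquipedalis", "cylindrica"
  )
  tibble::tibble(chrom = loci$chrom, start = loci$start,
                 end = loci$start + width - 1,
                 pop_a = loci$pop_a, pop_b = loci$pop_b, fst = fst)
}

#' Simulation configuration for a GBS-like structured cohort
#'
#' Assembles and validates the parameters of the Balding-Nichols cohort
#' generator. The defaults emulate the study cohort this package was built
#' around: 85 grain (`unguiculata`), 30 vegetable (`sesquipedalis`) and 13
#' fodder (`cylindrica`) accessions plus 2 wild outgroup samples; ~11,000
#' SNPs in GBS-style tag clusters over 11 chromosomes and one unmapped
#' contig; background divergence `f_background = 0.05` between cultivated
#' subspecies; twelve planted 250-kb islands at `f_island = 0.6`; 5%
#' missingness; and 5% each of indel, multiallelic and sub-MAF contaminant
#' records for the QC filter to remove.
#'
#' @param pop_sizes Named integer vector of diploid sample counts per
#'   population.
#' @param chrom_sizes Tibble (`chrom`, `length`); see [default_chrom_sizes()].
#' @param mapped_chroms Chromosomes considered assembled; others unmapped.
#' @param n_snps Total number of variant records to emit.
#' @param islands Island tibble as in [default_islands()]; may be empty.
#' @param f_background Background Balding-Nichols divergence per cultivated
#'   population (in `(0, 1)`).
#' @param f_island Default island divergence used by [default_islands()].
#' @param f_wild Divergence parameter of the wild outgroup.
#' @param ancestral_range Range of the uniform ancestral-frequency law.
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param indel_fraction,multiallelic_fraction,low_maf_fraction Fractions of
#'   `n_snps` emitted as each contaminant class.
#' @param cluster_mean Mean SNPs per GBS tag cluster (background placement).
#' @param cluster_span Maximum span of a tag cluster in bp.
#' @param island_clusters Tag clusters planted per island.
#' @param wild_label Population label receiving `f_wild`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(pop_sizes = c(unguiculata = 85, sesquipedalis = 30,
                                     cylindrica = 13, wild = 2),
                       chrom_sizes = default_chrom_sizes(),
                       mapped_chroms = sprintf("Vu%02d", 1:11),
                       n_snps = 11000,
                       islands = default_islands(),
                       f_background = 0.05,
                       f_island = 0.6,
                       f_wild = 0.3,
                       ancestral_range = c(0.05, 0.95),
                       missing_rate = 0.05,
                       indel_fraction = 0.05,
                       multiallelic_fraction = 0.05,
                       low_maf_fraction = 0.05,
                       cluster_mean = 5,
                       cluster_span = 800,
                       island_clusters = 6,
                       wild_label = "wild") {
  cfg <- list(pop_sizes = pop_sizes, chrom_sizes = chrom_sizes,
              mapped_chroms = mapped_chroms, n_snps = n_snps,
              islands = islands, f_background = f_background,
              f_island = f_island, f_wild = f_wild,
              ancestral_range = ancestral_range, missing_rate = missing_rate,
              indel_fraction = indel_fraction,
              multiallelic_fraction = multiallelic_fraction,
              low_maf_fraction = low_maf_fraction,
              cluster_mean = cluster_mean, cluster_span = cluster_span,
              island_clusters = island_clusters, wild_label = wild_label)
  fracs <- c(missing_rate, indel_fraction, multiallelic_fraction,
             low_maf_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (f_background <= 0 || f_background >= 1 || f_island <= 0 || f_island >= 1) {
    stop("divergence parameters must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(names(pop_sizes)) || any(pop_sizes < 1)) {
    stop("pop_sizes must be a named vector of positive counts", call. = FALSE)
  }
  if (nrow(islands)) {
    bad_chr <- setdiff(islands$chrom, chrom_sizes$chrom)
    if (length(bad_chr)) stop("island on unknown chromosome: ",
                              paste(bad_chr, collapse = ", "), call. = FALSE)
    L <- chrom_sizes$length[match(islands$chrom, chrom_sizes$chrom)]
    if (any(islands$start < 1 | islands$end > L)) {
      stop("island outside chromosome bounds", call. = FALSE)
    }
    bad_pop <- setdiff(c(islands$pop_a, islands$pop_b), names(pop_sizes))
    if (length(bad_pop)) stop("island references unknown population: ",
                              paste(bad_pop, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw of a subpopulation frequency vector
.bn_draw <- function(p, f) {
  out <- p
  drift <- f > 1e-6
  if (any(drift)) {
    pf <- p[drift]
    ff <- f[drift]
    out[drift] <- stats::rbeta(length(pf), pf * (1 - ff) / ff,
                               (1 - pf) * (1 - ff) / ff)
  }
  out
}

# clustered GBS-tag positions: n sites on a chromosome of length L; clusters
# are generated whole and the last one truncated, so no positional bias
.cluster_positions <- function(L, n, cluster_mean, cluster_span) {
  if (n <= 0) return(integer(0))
  pos <- integer(0)
  while (length(pos) < n) {
    ctr <- sample.int(max(1, L - cluster_span), 1)
    k <- 1L + stats::rpois(1, cluster_mean - 1)
    pos <- c(pos, ctr + sort(sample.int(cluster_span, min(k, cluster_span))))
  }
  sort(unique(pos[seq_len(n)]))
}

#' Simulate a structured GBS-like cohort with planted divergence islands
#'
#' Generates genotypes under the Balding-Nichols model: per site an ancestral
#' frequency `p` is drawn from the configured uniform law; each population's
#' frequency is drawn `Beta(p (1-F)/F, (1-p)(1-F)/F)` with `F` the island
#' divergence for the island's two populations inside an island and the
#' background divergence otherwise; diploid genotypes are binomial
#' (Hardy-Weinberg within population). SNPs are placed in GBS-style tag
#' clusters, each island additionally seeded with `island_clusters` clusters.
#' Indel, multiallelic and sub-MAF contaminant records are injected at
#' exactly `round(fraction * n_snps)` sites (outside islands), and uniform
#' missingness is applied. Everything is reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `divscan_sim`: `geno` ([geno()] container),
#'   `pop_map` (tibble `sample`, `population`), `truth` (list with `islands`,
#'   per-site `site_class` — background/island/indel/multiallelic/low_maf —
#'   `island_id`, and `pop_freq`, the true per-population frequency matrix),
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  cs <- cfg$chrom_sizes
  # contaminant budget, deterministic
  n_indel <- round(cfg$indel_fraction * cfg$n_snps)
  n_multi <- round(cfg$multiallelic_fraction * cfg$n_snps)
  n_lowmaf <- round(cfg$low_maf_fraction * cfg$n_snps)

  # island tag clusters first, then background placement proportional to
  # chromosome length with the remaining site budget
  isl_sites <- NULL
  if (nrow(cfg$islands)) {
    isl_sites <- purrr::map_dfr(seq_len(nrow(cfg$islands)), function(i) {
      isl <- cfg$islands[i, ]
      span <- cfg$cluster_span
      pos <- unlist(lapply(seq_len(cfg$island_clusters), function(k) {
        ctr <- isl$start + sample.int(max(1, isl$end - isl$start - span), 1)
        kk <- 1L + stats::rpois(1, cfg$cluster_mean - 1)
        ctr + sort(sample.int(span, min(kk, span)))
      }))
      tibble::tibble(chrom = isl$chrom, pos = as.integer(pos))
    })
  }
  n_bg <- max(0, cfg$n_snps - if (is.null(isl_sites)) 0 else nrow(isl_sites))
  alloc <- round(n_bg * cs$length / sum(cs$length))
  sites <- purrr::map_dfr(seq_len(nrow(cs)), function(i) {
    tibble::tibble(chrom = cs$chrom[i],
                   pos = .cluster_positions(cs$length[i], alloc[i],
                                            cfg$cluster_mean, cfg$cluster_span))
  })
  sites <- dplyr::bind_rows(sites, isl_sites) |>
    dplyr::distinct(.data$chrom, .data$pos) |>
    dplyr::arrange(match(.data$chrom, cs$chrom), .data$pos)
  ns <- nrow(sites)

  # island membership
  island_id <- integer(ns)
  if (nrow(cfg$islands)) {
    for (i in seq_len(nrow(cfg$islands))) {
      isl <- cfg$islands[i, ]
      hit <- sites$chrom == isl$chrom & sites$pos >= isl$start &
        sites$pos <= isl$end
      island_id[hit] <- i
    }
  }
  # contaminant classes drawn outside islands so planted signal is intact
  site_class <- rep("background", ns)
  site_class[island_id > 0] <- "island"
  free <- which(site_class == "background")
  n_cont <- n_indel + n_multi + n_lowmaf
  if (n_cont > length(free)) stop("too many contaminants for n_snps", call. = FALSE)
  pick <- sample(free, n_cont)
  site_class[pick[seq_len(n_indel)]] <- "indel"
  site_class[pick[n_indel + seq_len(n_multi)]] <- "multiallelic"
  site_class[pick[n_indel + n_multi + seq_len(n_lowmaf)]] <- "low_maf"

  # ancestral and per-population frequencies
  p <- stats::runif(ns, cfg$ancestral_range[1], cfg$ancestral_range[2])
  lowmaf <- site_class == "low_maf"
  p[lowmaf] <- stats::runif(sum(lowmaf), 0.002, 0.03)
  pops <- names(cfg$pop_sizes)
  cultivated <- setdiff(pops, cfg$wild_label)
  Fm <- matrix(cfg$f_background, ns, length(pops),
               dimnames = list(NULL, pops))
  if (cfg$wild_label %in% pops) Fm[, cfg$wild_label] <- cfg$f_wild
  if (nrow(cfg$islands)) {
    for (i in seq_len(nrow(cfg$islands))) {
      hit <- island_id == i
      Fm[hit, c(cfg$islands$pop_a[i], cfg$islands$pop_b[i])] <- cfg$islands$fst[i]
    }
  }
  pop_freq <- vapply(pops, function(po) .bn_draw(p, Fm[, po]), numeric(ns))

  # genotypes
  sample_pop <- rep(pops, cfg$pop_sizes)
  samples <- sprintf("%s_%03d", sample_pop, unlist(lapply(cfg$pop_sizes, seq_len)))
  G <- matrix(NA_integer_, ns, length(samples))
  for (po in pops) {
    idx <- which(sample_pop == po)
    G[, idx] <- stats::rbinom(ns * length(idx), 2L, rep(pop_freq[, po], length(idx)))
  }
  refs <- rep("A", ns)
  alts <- rep("T", ns)
  alts[site_class == "multiallelic"] <- "T,C"
  refs[site_class == "indel"] <- "AT"
  # missingness, uniform over calls
  n_miss <- round(cfg$missing_rate * length(G))
  if (n_miss > 0) G[sample(length(G), n_miss)] <- NA_integer_

  site_tab <- tibble::tibble(
    chrom = sites$chrom, pos = as.integer(sites$pos),
    id = sprintf("snp%05d", seq_len(ns)),
    ref = refs, alt = alts
  )
  g <- geno(site_tab, G, samples)
  g$sites$is_mapped <- g$sites$chrom %in% cfg$mapped_chroms
  structure(list(
    geno = g,
    pop_map = tibble::tibble(sample = samples, population = sample_pop),
    truth = list(islands = cfg$islands,
                 site_class = site_class,
                 island_id = island_id,
                 pop_freq = pop_freq),
    config = cfg
  ), class = "divscan_sim")
}

#' @export
print.divscan_sim <- function(x, ...) {
  cat(sprintf("<divscan_sim> %d sites x %d samples; %d island(s)\n",
              n_sites(x$geno), n_samples(x$geno), nrow(x$truth$islands)))
  print(table(x$truth$site_class))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `pops.tsv`, `sizes.tsv`, and the truth islands as
#' `islands_truth.bed` (BED with the island pair and F value in columns 4-5;
#' the `_truth` suffix marks these as simulator ground truth, not empirical
#' annotation).
#'
#' @param sim A `divscan_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$geno, file.path(dir, "cohort.vcf"),
            chrom_sizes = sim$config$chrom_sizes)
  readr::write_tsv(sim$pop_map, file.path(dir, "pops.tsv"), col_names = FALSE)
  readr::write_tsv(sim$config$chrom_sizes, file.path(dir, "sizes.tsv"),
                   col_names = FALSE)
  isl <- sim$truth$islands
  bed <- tibble::tibble(chrom = isl$chrom, start = as.integer(isl$start - 1),
                        end = as.integer(isl$end),
                        name = paste(isl$pop_a, isl$pop_b, sep = "-"),
                        fst = isl$fst)
  readr::write_tsv(bed, file.path(dir, "islands_truth.bed"), col_names = FALSE)
  invisible(dir)
}

#' Score called peaks against the planted truth
#'
#' Sensitivity is the fraction of planted islands overlapped (>= 1 bp) by at
#' least one called peak; precision is the fraction of called peaks
#' overlapping at least one island. Peaks from all pairwise comparisons are
#' pooled: an island planted for one pair also raises the divergence of its
#' two populations from the third, so any peak inside the island interval is
#' a genuine rediscovery of planted structure. With no called peaks,
#' precision is vacuous and reported as 1 with `precision_defined = FALSE`.
#'
#' @param peaks Peak tibble (e.g. `tidy()` of a [scan_divergence()] result).
#' @param truth_islands Island tibble (`chrom`, `start`, `end`).
#' @return A list of class `divscan_recovery`: `sensitivity`, `precision`,
#'   `precision_defined`, and `island_hits` (per-island hit table).
#' @export
recovery_report <- function(peaks, truth_islands) {
  isl <- truth_islands
  hit <- vapply(seq_len(nrow(isl)), function(i) {
    any(peaks$chrom == isl$chrom[i] &
          peaks$start <= isl$end[i] & peaks$end >= isl$start[i])
  }, logical(1))
  prec_def <- nrow(peaks) > 0
  prec <- if (!prec_def) 1 else mean(vapply(seq_len(nrow(peaks)), function(j) {
    any(isl$chrom == peaks$chrom[j] &
          isl$start <= peaks$end[j] & isl$end >= peaks$start[j])
  }, logical(1)))
  structure(list(
    sensitivity = if (nrow(isl)) mean(hit) else NA_real_,
    precision = prec,
    precision_defined = prec_def,
    island_hits = dplyr::bind_cols(isl, tibble::tibble(hit = hit))
  ), class = "divscan_recovery")
}

#' @export
print.divscan_recovery <- function(x, ...) {
  cat(sprintf("<divscan_recovery> sensitivity %.3f, precision %.3f%s\n",
              x$sensitivity, x$precision,
              if (!x$precision_defined) " (vacuous: no peaks)" else ""))
  invisible(x)
}
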