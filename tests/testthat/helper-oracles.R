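# Independent oracles, written as literal transcriptions of the published
# formulas (scalar loops, no shared code with the implementation), plus small
# fixture builders.

# Weir & Cockerham (1984) two-population diploid a, b, c for ONE site.
# g1, g2: dosage vectors (0/1/2, NA missing) for the two populations.
wc_site_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(list(a = NA, b = NA, c = NA, fst = NA))
  r <- 2
  ni <- c(n1, n2)
  pi_ <- c(sum(g1) / (2 * n1), sum(g2) / (2 * n2))
  hi <- c(sum(g1 == 1) / n1, sum(g2 == 1) / n2)
  nbar <- sum(ni) / r
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi_) / (r * nbar)
  s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(list(a = 0, b = 0, c = 0, fst = NA))
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc > 0) a / (a + b + cc) else NA)
}

# Nucleotide diversity of one site by enumeration of all allele pairs.
pi_site_oracle <- function(dos) {
  dos <- dos[!is.na(dos)]
  alleles <- unlist(lapply(dos, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(0)
  diff_count <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diff_count <- diff_count + (alleles[i] != alleles[j])
  }
  # 2 * diff_count / (n (n-1)) equals diff_count / choose(n, 2)
  2 * diff_count / (n * (n - 1))
}

# squared Pearson correlation of two dosage vectors, complete cases, by the
# textbook sum formulas
r2_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  vx <- sum(x^2) - sx^2 / n
  vy <- sum(y^2) - sy^2 / n
  if (vx == 0 || vy == 0) return(NA_real_)
  cxy <- sum(x * y) - sx * sy / n
  (cxy / sqrt(vx * vy))^2
}

# quadratic all-pairs interval overlap (1-based closed)
overlap_oracle <- function(q, ivs) {
  hits <- logical(nrow(ivs))
  for (j in seq_len(nrow(ivs))) {
    hits[j] <- ivs$chrom[j] == q$chrom &&
      ivs$start[j] <= q$end && q$start <= ivs$end[j]
  }
  which(hits)
}

# random geno fixture on a single chromosome
rand_geno <- function(ns = 20, nsamp = 8, miss = 0.1, chrom = "Vu01",
                      L = 1e6) {
  pos <- sort(sample.int(L, ns))
  dos <- matrix(sample(0:2, ns * nsamp, replace = TRUE), ns, nsamp)
  if (miss > 0) dos[sample(length(dos), round(miss * length(dos)))] <- NA
  geno(tibble::tibble(chrom = chrom, pos = pos), dos,
       sprintf("s%02d", seq_len(nsamp)))
}

# two-population map for a geno's samples, first n1 samples in pop "A"
pair_map <- function(g, n1) {
  tibble::tibble(sample = g$samples,
                 population = rep(c("A", "B"),
                                  c(n1, n_samples(g) - n1)))
}

# tiny config for fast simulator-backed tests
small_sim_config <- function(...) {
  sim_config(
    pop_sizes = c(unguiculata = 30, sesquipedalis = 15, cylindrica = 8),
    chrom_sizes = tibble::tibble(chrom = c("Vu01", "Vu02", "contig_unmapped"),
                                 length = c(40e6, 30e6, 10e6)),
    mapped_chroms = c("Vu01", "Vu02"),
    n_snps = 2000,
    islands = tibble::tibble(
      chrom = c("Vu01", "Vu02"), start = c(10e6, 5e6),
      end = c(10.25e6, 5.25e6),
      pop_a = "unguiculata", pop_b = "sesquipedalis", fst = 0.6),
    ...
  )
}
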