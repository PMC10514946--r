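# small two-population cohort with one strong divergence cluster
scan_fixture <- function(seed = 1, n1 = 20, n2 = 15, L = 2e6, ns = 120) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(L, ns))
    p <- stats::runif(ns, 0.1, 0.9)
    d1 <- matrix(stats::rbinom(ns * n1, 2, rep(p, n1)), ns, n1)
    d2 <- matrix(stats::rbinom(ns * n2, 2, rep(p, n2)), ns, n2)
    # plant a divergent cluster of 6 sites near 1 Mb
    isl <- which(pos >= 1e6 & pos <= 1.1e6)[1:6]
    isl <- isl[!is.na(isl)]
    d1[isl, ] <- matrix(stats::rbinom(length(isl) * n1, 2, 0.05), length(isl), n1)
    d2[isl, ] <- matrix(stats::rbinom(length(isl) * n2, 2, 0.95), length(isl), n2)
    g <- geno(tibble::tibble(chrom = "Vu01", pos = pos),
              cbind(d1, d2), sprintf("s%02d", seq_len(n1 + n2)))
    list(g = g, pm = pair_map(g, n1), isl_pos = pos[isl])
  })
}

test_that("permutation threshold is deterministic given the seed and hits the alpha edge", {
  fx <- scan_fixture()
  w <- make_windows(tibble::tibble(chrom = "Vu01", length = 2e6))
  t1 <- permutation_threshold(fx$g, fx$pm, c("A", "B"), w,
                              n_permutations = 30, seed = 99)
  t2 <- permutation_threshold(fx$g, fx$pm, c("A", "B"), w,
                              n_permutations = 30, seed = 99)
  expect_identical(t1$threshold, t2$threshold)

  # one site permutation replayed externally: threshold is exactly the
  # (1 - alpha) quantile of the permuted window values; alpha = 1 the minimum
  comp <- wc_components(fx$g, fx$pm, c("A", "B"))
  o <- withr::with_seed(77L, sample.int(nrow(comp)))
  comp_perm <- comp
  comp_perm[c("a", "b", "c", "fst", "usable")] <-
    comp[o, c("a", "b", "c", "fst", "usable")]
  ws_perm <- windowed_fst(comp_perm, w, mode = "weighted")$fst
  ws_perm <- ws_perm[!is.na(ws_perm)]
  for (al in c(1, 0.5, 0.001)) {
    # a single replayed permutation under-resolves small alpha by design here
    thr <- suppressWarnings(
      permutation_threshold(fx$g, fx$pm, c("A", "B"), w, alpha = al,
                            n_permutations = 1, seed = 77, min_sites = 1))
    expect_equal(thr$threshold,
                 stats::quantile(ws_perm, 1 - al, names = FALSE))
  }
  # extreme alpha with few permutations warns
  expect_warning(
    permutation_threshold(fx$g, fx$pm, c("A", "B"), w, alpha = 1e-9,
                          n_permutations = 3, seed = 1), "small")
})

test_that("label and site schemes both leave the planted cluster above threshold", {
  fx <- scan_fixture()
  w <- make_windows(tibble::tibble(chrom = "Vu01", length = 2e6))
  comp <- wc_components(fx$g, fx$pm, c("A", "B"))
  ws <- windowed_fst(comp, w, mode = "weighted")
  for (sch in c("site", "label")) {
    thr <- permutation_threshold(fx$g, fx$pm, c("A", "B"), w, alpha = 0.001,
                                 n_permutations = 50, seed = 2, scheme = sch)
    fl <- call_outlier_windows(ws, thr)
    expect_gt(nrow(fl), 0)
    expect_true(any(fl$start <= min(fx$isl_pos) & fl$end >= min(fx$isl_pos)))
  }
})

test_that("outlier calling uses strict inequality and respects min_sites", {
  ws <- tibble::tibble(chrom = "c1", start = c(1, 11, 21), end = c(10, 20, 30),
                       n_sites = c(5L, 5L, 0L), fst = c(0.5, 0.3, NA),
                       mean_fst = NA, weighted_fst = NA)
  fl <- call_outlier_windows(ws, 0.5, min_sites = 1)
  expect_equal(nrow(fl), 0)          # tie goes to non-outlier
  fl2 <- call_outlier_windows(ws, 0.4, min_sites = 1)
  expect_equal(fl2$start, 1)
  fl3 <- call_outlier_windows(ws, 0, min_sites = 1)
  expect_equal(nrow(fl3), 2)         # NA window never flagged
  # hand-built vector with 3 exceedances
  ws3 <- tibble::tibble(chrom = "c1", start = seq(1, 51, 10),
                        end = seq(10, 60, 10),
                        n_sites = 3L, fst = c(.9, .1, .8, .2, .85, .3))
  expect_equal(call_outlier_windows(ws3, 0.7, min_sites = 1)$fst,
               c(.9, .8, .85))
})

test_that("peak merging follows runs, SNP boundaries and flank arithmetic", {
  # flags at grid starts 10001, 20001, 50001 -> two peaks (gap breaks the run)
  fl <- tibble::tibble(chrom = "Vu08",
                       start = c(10001, 20001, 50001),
                       end = c(110000, 120000, 150000),
                       n_sites = 2L, fst = c(0.9, 0.95, 0.85))
  sites <- tibble::tibble(chrom = "Vu08",
                          pos = c(15000L, 60000L, 100000L, 130000L))
  pk <- merge_peaks(fl, sites, step = 10000)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$n_windows, c(2L, 1L))
  expect_equal(pk$mean_fst, c(mean(c(0.9, 0.95)), 0.85))

  # single flagged window holding SNPs at 33,036,301 and 33,036,620
  fl2 <- tibble::tibble(chrom = "Vu08", start = 33000001, end = 33100000,
                        n_sites = 2L, fst = 0.93)
  s2 <- tibble::tibble(chrom = "Vu08", pos = c(33036301L, 33036620L))
  pk2 <- merge_peaks(fl2, s2)
  expect_equal(pk2$start, 33036301)
  expect_equal(pk2$end, 33036620)
  expect_equal(pk2$length, 319)
  expect_equal(pk2$flank_start, 32986301)
  expect_equal(pk2$flank_end, 33086301)
  expect_equal(pk2$flank_end - pk2$flank_start, 100000)

  # degenerate peak: one SNP -> zero length
  pk3 <- merge_peaks(fl2, s2[1, ])
  expect_equal(pk3$length, 0)

  # window-midpoint boundaries
  pk4 <- merge_peaks(fl2, s2, boundary_mode = "window_midpoint")
  expect_equal(pk4$start, floor((33000001 + 33100000) / 2))

  # empty flag list -> empty peaks, not an error
  expect_equal(nrow(merge_peaks(fl2[0, ], s2)), 0)

  # flank clipped at chromosome bounds gets flagged
  fl5 <- tibble::tibble(chrom = "Vu08", start = 1, end = 100000,
                        n_sites = 1L, fst = 0.9)
  pk5 <- merge_peaks(fl5, tibble::tibble(chrom = "Vu08", pos = 5000L),
                     chrom_sizes = tibble::tibble(chrom = "Vu08", length = 38e6))
  expect_true(pk5$flank_clipped)
  expect_equal(pk5$flank_start, 1)
})

test_that("scan is deterministic and alpha is monotone in flagged windows", {
  fx <- scan_fixture()
  cs <- tibble::tibble(chrom = "Vu01", length = 2e6)
  sc1 <- scan_divergence(fx$g, fx$pm, c("A", "B"), cs,
                         n_permutations = 40, seed = 5)
  sc2 <- scan_divergence(fx$g, fx$pm, c("A", "B"), cs,
                         n_permutations = 40, seed = 5)
  expect_identical(tidy(sc1), tidy(sc2))
  expect_identical(sc1$thresholds$threshold, sc2$thresholds$threshold)

  # lowering alpha never increases the number of flagged windows
  w <- make_windows(cs)
  comp <- wc_components(fx$g, fx$pm, c("A", "B"))
  ws <- windowed_fst(comp, w, mode = "weighted")
  n_flagged <- vapply(c(0.05, 0.01, 0.001), function(al) {
    thr <- permutation_threshold(fx$g, fx$pm, c("A", "B"), w, alpha = al,
                                 n_permutations = 50, seed = 3)
    nrow(call_outlier_windows(ws, thr))
  }, numeric(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("peak members all exceed the threshold and no two peaks share a window", {
  fx <- scan_fixture(seed = 4)
  cs <- tibble::tibble(chrom = "Vu01", length = 2e6)
  sc <- scan_divergence(fx$g, fx$pm, c("A", "B"), cs,
                        n_permutations = 60, seed = 11)
  thr <- sc$thresholds$threshold[1]
  pk <- tidy(sc)
  if (nrow(pk)) {
    expect_true(all(pk$mean_fst > thr))
    expect_equal(sum(pk$n_windows),
                 nrow(call_outlier_windows(
                   sc$windows, sc$thresholds$threshold[1],
                   min_sites = sc$params$min_sites)))
    # flank width exactly 100 kb when not clipped
    unclipped <- !pk$flank_clipped
    expect_true(all((pk$flank_end - pk$flank_start)[unclipped] == 1e5))
  }
})
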