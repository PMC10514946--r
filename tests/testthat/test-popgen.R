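test_that("window grid follows the size/step/truncation rules", {
  cs <- tibble::tibble(chrom = "c1", length = 120000)
  w <- make_windows(cs)
  expect_equal(nrow(w), 12)
  expect_equal(w$start[1:3], c(1, 10001, 20001))
  expect_true(all(w$end <= 120000))
  expect_true(all(diff(w$start) == 10000))

  w2 <- make_windows(tibble::tibble(chrom = "c1", length = 50000))
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(1, 50000))

  w3 <- make_windows(tibble::tibble(chrom = "c1", length = 1e6),
                     size = 1e5, step = 1e5)
  expect_equal(nrow(w3), 10)
  expect_true(all(w3$start[-1] == utils::head(w3$end, -1) + 1))
})

test_that("fixed difference gives F_ST 1 and identical populations give sum(a) <= 0", {
  g <- geno(tibble::tibble(chrom = "c1", pos = c(10L, 20L)),
            rbind(c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L)),
            paste0("s", 1:4))
  comp <- wc_components(g, pair_map(g, 2), c("A", "B"))
  expect_equal(comp$fst, c(1, 1))

  withr::local_seed(5)
  dup <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  g2 <- geno(tibble::tibble(chrom = "c1", pos = 1:20 * 10L),
             cbind(dup, dup), paste0("s", 1:4))
  comp2 <- wc_components(g2, pair_map(g2, 2), c("A", "B"))
  expect_lte(sum(comp2$a), 1e-12)
})

test_that("components match the literal Weir-Cockerham oracle on random instances", {
  withr::local_seed(101)
  for (k in 1:60) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    ns <- sample(1:10, 1)
    dos <- matrix(sample(c(0:2, NA), ns * (n1 + n2), replace = TRUE,
                         prob = c(.3, .3, .3, .1)), ns, n1 + n2)
    # ensure both pops have >= 2 calls at >= 1 site
    dos[1, ] <- sample(0:2, n1 + n2, replace = TRUE)
    g <- geno(tibble::tibble(chrom = "c1", pos = seq_len(ns) * 10L), dos,
              paste0("s", seq_len(n1 + n2)))
    comp <- wc_components(g, pair_map(g, n1), c("A", "B"))
    for (s in seq_len(ns)) {
      o <- wc_site_oracle(dos[s, seq_len(n1)], dos[s, n1 + seq_len(n2)])
      if (is.na(o$a)) {
        expect_false(comp$usable[s])
      } else {
        expect_equal(comp$a[s], o$a, tolerance = 1e-12)
        expect_equal(comp$b[s], o$b, tolerance = 1e-12)
        expect_equal(comp$c[s], o$c, tolerance = 1e-12)
      }
    }
  }
})

test_that("wc_components errors when a population never has 2 called genotypes", {
  g <- geno(tibble::tibble(chrom = "c1", pos = c(10L, 20L)),
            rbind(c(0L, NA, 1L, 2L), c(1L, NA, 0L, 2L)), paste0("s", 1:4))
  expect_error(wc_components(g, pair_map(g, 2), c("A", "B")),
               "fewer than 2")
})

test_that("windowed F_ST matches per-window oracle and the two modes agree when they must", {
  withr::local_seed(7)
  g <- rand_geno(ns = 5, nsamp = 12, miss = 0.05, L = 90000)
  comp <- wc_components(g, pair_map(g, 6), c("A", "B"))
  w <- make_windows(tibble::tibble(chrom = "Vu01", length = 90000))
  ws <- windowed_fst(comp, w)
  expect_equal(nrow(ws), 1)
  u <- comp$usable
  expect_equal(ws$mean_fst, mean(comp$fst[u]))
  expect_equal(ws$weighted_fst,
               sum(comp$a[u]) / sum((comp$a + comp$b + comp$c)[u]))
  expect_equal(ws$fst, ws$mean_fst)  # default mode

  # single usable site: both summaries equal that site's ratio
  g1 <- g[which(u)[1], ]
  c1 <- wc_components(g1, pair_map(g, 6), c("A", "B"))
  w1 <- windowed_fst(c1, w, mode = "weighted")
  expect_equal(w1$mean_fst, w1$weighted_fst)
  expect_equal(w1$fst, c1$fst[1])
})

test_that("windowed statistics are invariant to sample and site order", {
  withr::local_seed(21)
  g <- rand_geno(ns = 30, nsamp = 14, miss = 0.1, L = 400000)
  pm <- pair_map(g, 7)
  w <- make_windows(tibble::tibble(chrom = "Vu01", length = 400000))
  base_fst <- windowed_fst(wc_components(g, pm, c("A", "B")), w)
  base_pi <- windowed_pi(g, w)

  perm_s <- sample(n_samples(g))
  gs <- g[, perm_s]
  expect_equal(windowed_fst(wc_components(gs, pm, c("A", "B")), w), base_fst)
  expect_equal(windowed_pi(gs, w), base_pi)

  perm_i <- sample(n_sites(g))
  gi <- g[perm_i, ]
  expect_equal(windowed_fst(wc_components(gi, pm, c("A", "B")), w), base_fst)
  expect_equal(windowed_pi(gi, w), base_pi)
})

test_that("every SNP falls in at most ceiling(size/step) windows of the grid", {
  cs <- tibble::tibble(chrom = "c1", length = 1e6)
  w <- make_windows(cs)
  withr::local_seed(3)
  pos <- sample.int(1e6, 200)
  hits <- vapply(pos, function(p) sum(w$start <= p & p <= w$end), integer(1))
  expect_true(all(hits <= 10))
  expect_true(all(hits >= 1))
})

test_that("site diversity matches the pairwise-difference oracle and scales per bp", {
  # 4 diploids, 8 alleles, 3 alternate: pi = 30/56
  g <- geno(tibble::tibble(chrom = "c1", pos = 500L),
            matrix(c(2L, 1L, 0L, 0L), 1, 4), paste0("s", 1:4))
  w <- tibble::tibble(chrom = "c1", start = 1, end = 1000)
  p <- windowed_pi(g, w)
  expect_equal(p$pi, (30 / 56) / 1000, tolerance = 1e-12)
  expect_equal(p$pi * 1000, pi_site_oracle(c(2L, 1L, 0L, 0L)), tolerance = 1e-12)

  # monomorphic window
  g0 <- geno(tibble::tibble(chrom = "c1", pos = 500L),
             matrix(0L, 1, 4), paste0("s", 1:4))
  expect_equal(windowed_pi(g0, w)$pi, 0)
})

test_that("single-site diversity approaches 2p(1-p) for large samples", {
  withr::local_seed(9)
  p <- 0.3
  dos <- matrix(stats::rbinom(500, 2, p), 1, 500)
  g <- geno(tibble::tibble(chrom = "c1", pos = 1L), dos, paste0("s", 1:500))
  w <- tibble::tibble(chrom = "c1", start = 1, end = 1)
  phat <- mean(dos) / 2
  expect_equal(windowed_pi(g, w)$pi, 2 * phat * (1 - phat),
               tolerance = 0.01)
})

test_that("windowed r2 reproduces the pairwise correlation oracle", {
  withr::local_seed(13)
  dos <- matrix(sample(0:2, 3 * 20, replace = TRUE), 3, 20)
  dos[2, 1:3] <- NA
  g <- geno(tibble::tibble(chrom = "c1", pos = c(10L, 20L, 30L)), dos,
            paste0("s", 1:20))
  w <- tibble::tibble(chrom = "c1", start = 1, end = 100)
  r <- windowed_r2(g, w)
  expected <- mean(c(r2_oracle(dos[1, ], dos[2, ]),
                     r2_oracle(dos[1, ], dos[3, ]),
                     r2_oracle(dos[2, ], dos[3, ])), na.rm = TRUE)
  expect_equal(r$mean_r2, expected, tolerance = 1e-12)

  # identical dosage vectors: r2 = 1
  g2 <- geno(tibble::tibble(chrom = "c1", pos = c(10L, 20L)),
             rbind(dos[1, ], dos[1, ]), paste0("s", 1:20))
  expect_equal(windowed_r2(g2, w)$mean_r2, 1)

  # single SNP: undefined
  expect_true(is.na(windowed_r2(g2[1, ], w)$mean_r2))
})
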