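test_that("config validation catches bad islands, fractions and divergence values", {
  expect_error(sim_config(f_background = 0), "\\(0, 1\\)")
  expect_error(sim_config(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(islands = tibble::tibble(
    chrom = "nope", start = 1, end = 10, pop_a = "unguiculata",
    pop_b = "sesquipedalis", fst = 0.6)), "unknown chromosome")
  expect_error(sim_config(islands = tibble::tibble(
    chrom = "Vu01", start = 1, end = 10, pop_a = "martian",
    pop_b = "sesquipedalis", fst = 0.6)), "unknown population")
  expect_error(sim_config(islands = tibble::tibble(
    chrom = "Vu01", start = 1, end = 99e6, pop_a = "unguiculata",
    pop_b = "sesquipedalis", fst = 0.6)), "bounds")
})

test_that("the same seed reproduces a byte-identical VCF", {
  cfg <- small_sim_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, seed = 12), d1)
  write_cohort(simulate_cohort(cfg, seed = 12), d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                   unname(tools::md5sum(file.path(d2, "cohort.vcf"))))
  # and a different seed does not
  write_cohort(simulate_cohort(cfg, seed = 13), d2)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                         unname(tools::md5sum(file.path(d2, "cohort.vcf")))))
})

test_that("contaminant counts equal the configured fractions exactly", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 2)
  cls <- table(sim$truth$site_class)
  expect_equal(unname(cls["indel"]), round(0.05 * cfg$n_snps))
  expect_equal(unname(cls["multiallelic"]), round(0.05 * cfg$n_snps))
  expect_equal(unname(cls["low_maf"]), round(0.05 * cfg$n_snps))
  expect_equal(sum(sim$geno$sites$is_indel), round(0.05 * cfg$n_snps))
  expect_equal(sum(sim$geno$sites$is_multiallelic), round(0.05 * cfg$n_snps))
  # missing calls are applied at the exact configured count
  expect_equal(sum(is.na(sim$geno$dosage)),
               round(cfg$missing_rate * length(sim$geno$dosage)))
})

test_that("the QC filter removes the planted indels/multiallelics and keeps islands", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 4)
  flt <- filter_sites(sim$geno)
  key <- paste(sim$geno$sites$chrom, sim$geno$sites$pos)
  kept <- key %in% paste(flt$geno$sites$chrom, flt$geno$sites$pos)
  cls <- sim$truth$site_class
  expect_true(all(!kept[cls == "indel"]))
  expect_true(all(!kept[cls == "multiallelic"]))
  # sub-MAF sites are removed in expectation; drift across the small cohort
  # lets a minority cross the 0.05 line
  expect_lt(mean(kept[cls == "low_maf"]), 0.25)
  # the filter keeps the bulk of background and island sites (strongly
  # drifted island sites can fall under the pooled-MAF rule)
  expect_gt(mean(kept[cls == "island"]), 0.6)
  expect_gt(mean(kept[cls == "background"]), 0.8)
})

test_that("panmictic limit yields near-zero genome-wide weighted F_ST", {
  cfg <- sim_config(pop_sizes = c(p1 = 40, p2 = 40),
                    chrom_sizes = tibble::tibble(chrom = "Vu01", length = 50e6),
                    mapped_chroms = "Vu01", n_snps = 3000,
                    islands = default_islands()[0, ],
                    f_background = 1e-4, missing_rate = 0,
                    indel_fraction = 0, multiallelic_fraction = 0,
                    low_maf_fraction = 0, wild_label = "none")
  sim <- simulate_cohort(cfg, seed = 5)
  comp <- wc_components(sim$geno, sim$pop_map, c("p1", "p2"))
  wfst <- sum(comp$a[comp$usable]) /
    sum((comp$a + comp$b + comp$c)[comp$usable])
  expect_lte(abs(wfst), 0.01)
})

test_that("weighted F_ST on Balding-Nichols data estimates the divergence parameter", {
  ests <- vapply(1:3, function(s) {
    cfg <- sim_config(pop_sizes = c(p1 = 50, p2 = 50),
                      chrom_sizes = tibble::tibble(chrom = "Vu01", length = 50e6),
                      mapped_chroms = "Vu01", n_snps = 2500,
                      islands = default_islands()[0, ],
                      f_background = 0.2, missing_rate = 0,
                      indel_fraction = 0, multiallelic_fraction = 0,
                      low_maf_fraction = 0, wild_label = "none")
    sim <- simulate_cohort(cfg, seed = 100 + s)
    comp <- wc_components(sim$geno, sim$pop_map, c("p1", "p2"))
    sum(comp$a[comp$usable]) / sum((comp$a + comp$b + comp$c)[comp$usable])
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lte(abs(mean(ests) - 0.2), max(3 * se, 0.01))
})

test_that("expected heterozygosity of background sites matches Balding-Nichols moments", {
  cfg <- sim_config(pop_sizes = c(p1 = 60),
                    chrom_sizes = tibble::tibble(chrom = "Vu01", length = 50e6),
                    mapped_chroms = "Vu01", n_snps = 4000,
                    islands = default_islands()[0, ],
                    f_background = 0.1, missing_rate = 0,
                    indel_fraction = 0, multiallelic_fraction = 0,
                    low_maf_fraction = 0, wild_label = "none")
  sim <- simulate_cohort(cfg, seed = 6)
  het <- mean(sim$geno$dosage == 1)
  # E[2 q (1-q)] with q ~ BN(p, F): 2 E[p(1-p)] (1-F), p ~ U(0.05, 0.95)
  pp <- function(p) p * (1 - p)
  epq <- stats::integrate(pp, 0.05, 0.95)$value / 0.9
  expected <- 2 * epq * (1 - 0.1)
  expect_equal(het, expected, tolerance = 0.03)
})

test_that("recovery report handles exact, empty and vacuous cases", {
  isl <- tibble::tibble(chrom = c("Vu01", "Vu02"), start = c(100, 200),
                        end = c(199, 299))
  pk_exact <- tibble::tibble(chrom = isl$chrom, start = isl$start,
                             end = isl$end)
  r <- recovery_report(pk_exact, isl)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)

  r0 <- recovery_report(pk_exact[0, ], isl)
  expect_equal(r0$sensitivity, 0)
  expect_equal(r0$precision, 1)
  expect_false(r0$precision_defined)

  # off-target peak: 1-bp overlap rule
  pk_mix <- tibble::tibble(chrom = c("Vu01", "Vu01"),
                           start = c(199, 5000), end = c(250, 6000))
  r2 <- recovery_report(pk_mix, isl)
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$precision, 0.5)
})

test_that("the end-to-end scan recovers planted islands on a small cohort", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 21)
  flt <- filter_sites(sim$geno)
  sc <- scan_divergence(flt$geno, sim$pop_map,
                        c("unguiculata", "sesquipedalis"),
                        cfg$chrom_sizes, n_permutations = 60, seed = 22)
  rec <- recovery_report(tidy(sc), sim$truth$islands)
  expect_gte(rec$sensitivity, 0.5)
  expect_gte(rec$precision, 0.5)
})
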