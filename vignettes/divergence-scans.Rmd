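---
title: "Windowed divergence scans with permutation-calibrated thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed divergence scans with permutation-calibrated thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
library(dplyr)
```

`divscan` implements a genome-scan workflow for small structured cohorts
genotyped by sequencing, of the kind used to compare crop subspecies: QC
filtering of a SNP matrix, windowed Weir–Cockerham F~ST~, nucleotide
diversity and LD r² on a 100 kb / 10 kb sliding grid,
permutation-calibrated outlier thresholds, divergence-peak calling with
flanking-region gene/QTL annotation, and population-structure summaries
(genotype PCA, Evanno ΔK, membership-threshold assignment). This vignette
explains the statistical model behind each stage, the defaults and why they
were chosen, and what the packaged simulation benchmark does and does not
demonstrate.

## The estimator

For two populations with, at a given biallelic site, $n_i$ called diploid
individuals, alternate-allele frequencies $\hat p_i$ and observed
heterozygote proportions $\hat h_i$, the package computes the Weir–Cockerham
(1984) variance components $a$ (among populations), $b$ (among individuals
within populations) and $c$ (within individuals), using per-site sample
sizes so missing genotypes simply reduce $n_i$ at that site. The per-site
fixation-index estimate is $\hat\theta = a/(a+b+c)$. Negative estimates are
retained — truncating them would bias window averages upward. A site enters
the calculation only when both populations have at least two called
genotypes; sites monomorphic across the pair carry zero components.

Two window summaries are computed over the usable SNPs in each window:

* `mean_fst` — the average of per-site ratios, the "average pairwise F~ST~
  per window" convention familiar from VCFtools output;
* `weighted_fst` — the ratio of sums $\sum a / \sum(a+b+c)$, Weir and
  Cockerham's own recommendation for combining loci, which weights each
  site by its information content.

Both are always reported. The *scan* thresholds on the weighted summary by
default: on simulated data with 250-kb islands at $F = 0.6$ over a
$F = 0.05$ background, mean-mode island windows average ≈ 0.39 — close to
per-site-ratio downward bias — while the weighted summary sits near the
island's true divergence (≈ 0.55–0.6) with less dispersion, which is what
separates islands from the permutation null. `mode = "mean"` restores the
averaged-ratio convention throughout.

Nucleotide diversity uses the unbiased per-site estimator
$\hat\pi = 2 n_{alt} n_{ref} / (n(n-1))$ over non-missing alleles and
normalises window sums by the full window span in bp, so invariant
positions dilute the estimate as in genome-windowed diversity scans. LD is
the squared Pearson correlation of genotype dosages over samples called at
both sites (composite, phase-free LD — GBS genotypes are unphased), averaged
over defined pairs per window; pairs in which either site has no dosage
variance in the complete-case subset are skipped.

## The permutation null

The scan asks: which windows are *more* divergent than the genome-wide
background? The null is built by permuting the per-site component records
across SNP positions genome-wide and recomputing the window statistic on
the same grid (`scheme = "site"`). All defined window values from all
permutations are pooled and the threshold is the empirical $1-\alpha$
quantile of the pool (default $\alpha = 0.001$), giving one genome-wide
threshold per comparison. This null preserves the marginal distribution of
per-site F~ST~ — including whatever genome-wide background divergence the
two populations have — and destroys only its arrangement along the genome.
A window is then an outlier when its SNPs are more *concordantly* divergent
than a random draw of the same number of SNPs from the whole genome.

An alternative null, `scheme = "label"`, reshuffles population labels among
the samples of the compared pair and recomputes everything. It nulls *all*
divergence, so with any appreciable background differentiation (subspecies
comparisons routinely have genome-wide F~ST~ of 0.05 and far more) a large
fraction of ordinary background windows exceeds its threshold: measured on
the default simulated cohort, the label-scheme threshold is ≈ 0.09 and
about 17% of background windows exceed it, which makes "outlier" a
meaningless label. The label scheme is appropriate only when the background
is expected to be panmictic, and is kept for that case.

Windows with fewer than `min_sites = 3` usable SNPs are excluded from both
the observed set and the null pool. One- and two-SNP windows carry unstable
single-site estimates, and because they are equally unstable in the
permuted pool they dominate its extreme tail and inflate the threshold for
everyone else (measured on the default cohort: threshold ≈ 0.65–0.71 with
`min_sites = 1` against ≈ 0.58 with `min_sites = 3`, at a substantial cost
in island sensitivity). Under the site scheme the per-window SNP count is
permutation-invariant, so this eligibility rule applies identically on both
sides and leaves the $\alpha$-calibration exact; `min_sites = 1` restores
the permissive behaviour.

Ties go to the null: a window exactly at the threshold is not an outlier.
All permutations derive from one integer seed, and identical inputs, seed
and parameters reproduce scan outputs byte for byte.

## Peaks and flanking regions

Maximal runs of grid-consecutive outlier windows (starts differing by
exactly the step) merge into one divergence peak. Peak boundaries default
to the first and last SNP inside the run's union span
(`boundary_mode = "snp"`): because outlier windows are driven by tight
marker clusters, peaks are then typically a few hundred bp — the scale at
which candidate regions are reported in practice. The alternative
`"window_midpoint"` mode uses the midpoints of the first and last member
windows. Each peak's `mean_fst` is the average of its member-window values.
The flanking interval is anchored at the peak start,
$[\mathrm{start} - 50\,\mathrm{kb},\ \mathrm{start} + 50\,\mathrm{kb}]$,
clipped (and flagged) at chromosome edges; gene and QTL annotation searches
this 100-kb flank, not the narrow peak, with ≥ 1 bp closed-interval
overlap.

## QC filter and density reporting

`filter_sites()` applies the standard GBS retention rules — drop indels,
multiallelic sites and sites monomorphic for a non-reference allele, sites
with missingness strictly above 10%, and sites with minor allele frequency
strictly below 0.05 (computed over non-missing alleles). Sites at exactly a
threshold are kept, a literal reading of "more than" / "below". Each
removed site is attributed to the first rule that triggers, in the order
indel → allele structure → missingness → MAF, so the report's counts
partition the input exactly; the headline attrition is reported as a
percentage to one decimal. The "non-reference allele" rule is genuinely
ambiguous in the filtering vocabulary this mirrors, so its two sub-rules
(multiallelic; monomorphic-ALT) are independently toggleable.

`density_summary()` produces the marker-density table: per-chromosome SNP
counts, sizes in Mbp, densities to two decimals, one pooled row for
unmapped contigs, a total row, and the mean ± sample (n−1) SD of the
mapped-chromosome densities.

## Structure summaries

`geno_pca()` mean-imputes missing dosages per site, centres, and
decomposes by SVD; variance fractions are eigenvalues over the trace
(summing to 100% across non-zero axes). Patterson scaling (dividing each
site by its binomial SD) is available but not the default, since dosage
PCA without variance scaling is the more common convention in crop
diversity panels and the choice rarely changes cluster topology. Axis signs
are fixed by orienting each axis so its largest-magnitude score is
positive, making results reproducible and invariant to site order.

`evanno_delta_k()` computes, per interior $K$,
$\Delta K = \mathrm{mean}_r\,|L_r(K{+}1) - 2L_r(K) + L_r(K{-}1)|\ /\
\mathrm{sd}_r\,L_r(K)$, with the second difference formed within each
replicate run and the SD taken across replicates (sample SD). A $K$ with
zero replicate SD yields a flagged `NA` rather than an error — a
noise-free table has no scale for the statistic. Endpoints are undefined.
`assignment_summary()` applies the strict `> 0.85` maximum-membership rule
and reports the assigned percentage to two decimals.

## The synthetic cohort

`simulate_cohort()` generates the statistical structure the scan assumes,
plus the contaminants the QC filter must remove, with a planted ground
truth for scoring. The model is Balding–Nichols: per site an ancestral
frequency $p \sim U(0.05, 0.95)$; each population's frequency is drawn
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so $F$ is (to first order) the
pairwise F~ST~ the scan estimates; genotypes are binomial within
populations (Hardy–Weinberg). Defaults mirror the cowpea cohort the
package was designed around: 85 grain + 30 vegetable + 13 fodder + 2 wild
samples; 11 chromosomes plus an unmapped contig at the reference assembly
sizes (≈ 519 Mb); ~11,000 SNPs; background $F = 0.05$ between cultivated
subspecies and $F = 0.3$ for the wild outgroup; 5% uniform missingness; 5%
each of indel, multiallelic and sub-MAF records (the latter with ancestral
frequencies in 0.002–0.03, so they fall below the MAF cut in expectation).

Two placement choices matter. SNPs are placed in GBS-style tag clusters
(cluster size $1 + \mathrm{Pois}(4)$ within ≤ 800 bp) rather than
uniformly: reduced-representation markers cluster at restriction sites,
and empirically reported divergence peaks are sub-kb runs of several SNPs.
Clustering is also what makes windowed statistics well-behaved at this
marker density — a uniform 11,000 SNPs over 519 Mb leaves ~2 SNPs per 100
kb window, too few for stable window estimates. Second, the twelve default
divergence islands (250 kb each, at loci echoing reported grain/vegetable
and vegetable/fodder peaks; nine affect the grain–vegetable pair, three
the vegetable–fodder pair) are each seeded with six marker clusters,
matching the several-sub-peaks-per-region structure of reported divergence
regions.

A deliberate modelling consequence: an island that drives its two
populations to $F = 0.6$ necessarily also raises their divergence from the
third population (to roughly $(0.6 + 0.05)/2$). Exactly pair-specific
divergence with a quiet third population is not realisable in any
allele-frequency model — if A and B separate, at least one of them moves
away from C. `recovery_report()` therefore pools peaks across comparisons
and scores interval overlap: a peak called in a "cross" pair inside a
planted island is a genuine rediscovery of planted structure. For the same
reason a pair with no planted islands is only *approximately* peak-free —
a genome-wide $\alpha = 0.001$ threshold implies about $\alpha N$ false
windows by construction.

What passing the benchmark shows — and does not. The simulation has no LD
beyond island-level frequency correlation, no structured (depth-dependent)
missingness, no allele-calling error, and islands are planted at known
strength; recovery of ≥ 90% sensitivity and precision under these
conditions validates the *mechanics* of estimator, null and peak logic, not
performance on real GBS data, where background heterogeneity, bottlenecks
and introgression can mimic or mask islands.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(), seed = 42)
flt <- filter_sites(sim$geno)
flt$report

sc <- scan_divergence(flt$geno, sim$pop_map,
                      c("unguiculata", "sesquipedalis", "cylindrica"),
                      sim$config$chrom_sizes,
                      n_permutations = 200, seed = 7)
glance(sc)          # one row per comparison: threshold, outliers, peaks
tidy(sc)            # the peak table
recovery_report(tidy(sc), sim$truth$islands)
plot_fst_windows(sc)
```

The same stages run from files via `run_full_analysis(run_config(...))`,
which writes the filter report, density table, per-pair window TSVs,
thresholds, the annotated peak table, PCA coordinates and a manifest with
parameters, seed, package version and input checksums; identical
configuration and inputs reproduce every output byte for byte.

## Numerical and design notes

* Thresholds, quantiles: empirical type-7 quantiles of the pooled null;
  threshold comparisons are strict (`>`).
* Permutations, simulation draws and PCA all derive from explicit integer
  seeds threaded through `withr::with_seed`; no global RNG state is
  consumed or disturbed.
* Problem sizes in the packaged checks: the oracle comparison uses 200
  random ≤10×10 instances; simulator calibration 10 cohorts of 5,000 SNPs ×
  100 samples at $F=0.2$; null calibration one 220-Mb chromosome tiled into
  ~2,100 non-overlapping 100-kb windows (tiling keeps window exceedances
  independent, so a binomial error band is valid) at $B=200$; recovery five
  full default cohorts at $B=200$. These sizes give Monte-Carlo error
  comfortably below the decision margins while keeping the whole suite in a
  few minutes.
* Windows are 1-based inclusive; a SNP at position $p$ belongs to window
  $(s, e)$ iff $s \le p \le e$. BED input is converted to this convention
  on read, GFF3 is native to it.
* Degenerate inputs: an all-sites-removed filter result is a warning with
  an empty container, not an error; a window grid on a chromosome shorter
  than the window size is a single truncated window; an empty peak list
  annotates to a header-only table; zero replicate SD in ΔK flags the value
  rather than failing.

## Limitations

The two-population estimator is implemented for pairs (the three-subspecies
analysis is the three pairwise comparisons, as in the study design this
mirrors); a multi-population joint estimator is not provided. D~XY~ and
haplotype-based LD are out of scope. STRUCTURE itself is not run — the ΔK
and assignment tools consume its (or any equivalent) likelihood and
membership tables.
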