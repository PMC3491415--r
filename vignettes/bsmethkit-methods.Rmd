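---
title: "Methods and design of bsmethkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of bsmethkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmethkit)
```

## The measurement and its data model

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while methylated cytosine is protected, so after alignment each cytosine
position in a sample carries two read counts: `n_meth` (C read-outs) and
`n_unmeth` (T read-outs).  The methylation level of the position is
`100 * n_meth / (n_meth + n_unmeth)` percent.  `bsmethkit` stores one
sample as a `methylome`: a sorted, duplicate-free table of units — single
cytosines (`resolution = "base"`) or summarized regions
(`resolution = "region"`) — each with a chromosome, a 1-based inclusive
start/end, a strand, and the two counts.  All coordinates are 1-based
inclusive internally; BED input (0-based half-open) is converted by
`read_features()` on read, and bedGraph output converts back on write.

Two ingestion routes exist.  The text route (`read_methylation_text()`)
parses a tab-separated per-base dialect with columns `chrBase, chr, base,
strand, coverage, freqC, freqT`; counts are re-derived as
`n_meth = round(coverage * freqC / 100)` with *half-up* rounding (base R's
`round()` rounds half to even, which would not reproduce the printed
percentages for some coverages).  Rows whose `freqC + freqT` deviate from
100 by more than 0.05 are rejected — the tolerance covers two-decimal
rounding of the two frequencies.  The SAM route (`read_bismark_sam()`)
consumes Bismark-style alignments whose `XM` tag spells per-read-base
calls (`Z/z` CpG, `X/x` CHG, `H/h` CHH); calls below the base-quality
threshold are excluded and positions below the coverage threshold are
dropped.  The defaults — at least 10 reads per position, PHRED quality at
least 20 per call — are the package-wide filtering defaults
(`filter_policy()`).

### Numerical and convention choices

* **Counts from percentages.** The text dialect stores frequencies, not
  counts; half-up rounding of `coverage * freqC / 100` is used because it
  reproduces the original counts exactly whenever the frequencies were
  themselves produced by two-decimal rounding of a count ratio.
* **Strand letters.** `F/R` and `+/-` are accepted on input; `+/-` are
  emitted.
* **High-coverage filter.** PCR duplication bias (clonal reads) inflates
  a secondary high-coverage mode; `filter_policy(high_coverage_percentile
  = 99.9)` removes units strictly above the empirical percentile (type-7
  quantile) of the sample's own coverage distribution, retaining ties at
  the cut.  Because the percentile is recomputed from whatever
  distribution the filter sees, re-applying the upper cut to already
  filtered data can, on pathological tie-free distributions, remove
  further units; the coverage floor is strictly idempotent.  In practice
  integer coverage data is heavily tied and the cut is stable.
* **No implicit filtering.** The text reader never applies the coverage
  floor; filtering is always an explicit `filter_by_coverage()` step, so
  tables that were already processed upstream pass through unaltered.
* **Duplicate read handling.** The SAM reader does not collapse PCR
  duplicates (alignment-level deduplication is upstream of this
  package); the high-coverage percentile filter is the provided
  mitigation.

## Regional summarization

`tile_methylome()` lays windows per chromosome **anchored at position
1**, stepping by `step_size`; a window's counts are sums over the covered
cytosines it contains, and windows with fewer than `min_bases` covered
cytosines are dropped.  Anchoring at 1 (rather than at the first covered
base) makes tile coordinates a pure function of the parameters, so tiles
are comparable across samples without further alignment.  With
`step_size < window_size` windows overlap and bases intentionally
contribute to every window containing them.  `summarize_regions()` does
the same over user intervals; a base inside two overlapping regions
contributes to both, since no precedence is defined for summarization.
Both emit `resolution = "region"` methylomes that flow through the rest
of the package unchanged.  Defaults are 1000 bp non-overlapping windows,
a common tiling choice; `min_bases` defaults to 1 but is exposed because
sparse tiles are statistically fragile.

`unite_methylomes()` joins N samples on the intersection of unit keys —
only units covered in **every** sample are kept, and nothing is ever
imputed.  All cross-sample statistics (correlation, clustering, PCA,
differential testing) operate on this complete-case container.  Optional
CpG destranding (`destrand()`) merges the two strands of a CpG dyad onto
the forward-strand coordinate; it defaults off so that strand-level
signal is not silently pooled.

## Sample characterization

`methylation_stats()` and `coverage_stats()` provide the two standard
per-sample views: the percent-methylation histogram (bimodal in normal
samples) and the coverage histogram (a second right-hand mode indicates
clonal reads).  `correlation_matrix()` supports Pearson, Kendall and
Spearman on the percent matrix; zero-variance samples yield `NA` entries
with a warning rather than a silent 0.  `cluster_samples()` exposes the
`1 - Pearson correlation` distance plus the usual geometric metrics
(euclidean, maximum, manhattan, canberra, binary, minkowski) and ward /
single / complete / average linkage.  "Ward" maps to the squared-distance
update (`ward.D2`); the classical description of Ward's method does not
pin down the variant, and `ward.D2` is the one consistent with
untransformed dissimilarities.  `pca_samples()` treats samples as
observations and units as variables (`center = TRUE`, `scale. = FALSE` by
default — percent units are already commensurable, so variance scaling is
not imposed).  Each component's sign is fixed by forcing its
largest-magnitude loading positive, making scores reproducible across
BLAS/platforms.

## Differential methylation

At each unit the methylation proportion $P_i$ of sample $i$ is modeled as

$$\log\frac{P_i}{1-P_i} = \beta_0 + \beta_1 T_i
  + \alpha_1 \mathrm{Cov}_{1,i} + \dots + \alpha_K \mathrm{Cov}_{K,i},$$

with per-sample binomial counts (`n_meth` successes out of coverage) and
$T_i$ the treatment indicator ($T_i = 0$ for controls).  The null
$\beta_1 = 0$ is tested by the likelihood-ratio (deviance) chi-square by
default; a Wald test is available.  The effective sample size here is
the *total read coverage per group*, not the number of biological
replicates, which is why the test retains power with few samples at
adequate depth.  Design choices:

* **Likelihood-ratio by default.** The model and null hypothesis admit
  several statistics; the deviance test is used because it remains
  finite under complete separation (pooled proportions 0 vs 1), where
  the Wald statistic degenerates.  Separated units are flagged
  (`flagged = TRUE`) and their `beta1` is reported as infinite.
* **Fast path.** Without covariates the group-wise MLEs are the pooled
  group proportions, so the deviance statistic has a closed form that is
  vectorized across units; with covariates each unit is fitted by
  `glm()`.  The two routes agree to machine precision and are
  cross-checked in the tests against direct numerical likelihood
  maximization.
* **Effect size.** `meth.diff` is computed from pooled group counts,
  `100 (\sum_T m / \sum_T c - \sum_C m / \sum_C c)` — the
  coverage-weighted quantity matched to the binomial model — not the
  mean of per-sample percentages.
* **Multiple groups.** Treatment enters as a categorical factor with
  control (0) as reference; the overall test has `#groups - 1` degrees
  of freedom.
* **Dispatch.** With exactly one sample per group a regression on two
  binomial observations has no replication to exploit, so
  `calculate_diff_meth()` switches to Fisher's exact test on the 2x2
  table; with replicates anywhere it uses the logistic test.  Fisher is
  *only* used for true 1-vs-1 designs — replicates are never silently
  pooled into a 2x2 table.
* **Fisher's test.** Two-sided by the point-probability rule: all tables
  (conditional on margins) with hypergeometric probability at most that
  of the observed table, with a `1 + 1e-7` relative guard against
  floating-point ties.  The implementation enumerates the conditional
  support directly and is verified exhaustively against an independent
  log-binomial-coefficient enumeration for all margins up to 30.
* **No overdispersion correction.** Between-replicate variance beyond
  binomial is not modeled; this is a known limitation (see below).
* **Parallelism.** Units are chunked by position, chunks are processed
  by forked workers, and results are concatenated in unit order, so the
  output is bit-identical for any worker count.

### q-values

`adjust_pvalues()` implements Benjamini-Hochberg (via `p.adjust`) and the
default SLIM-style correction.  SLIM estimates $\pi_0$, the proportion of
true nulls, from the empirical CDF of the p-values: away from the
signal-bearing left tail the CDF of null p-values grows linearly with
slope $\pi_0$, so OLS lines are fitted over sliding windows (starts 0.30
to 0.70 in steps of 0.05, width 0.20, CDF evaluated every 0.01) and the
median slope, clamped to $[0,1]$, is $\hat\pi_0$.  Then
$q = \hat\pi_0 \, q_{BH}$, which is never more conservative than BH.
The median across windows (rather than the minimum) trades a little
anti-conservatism for stability on small inputs; with fewer than 20
p-values, or a degenerate fit, $\hat\pi_0$ falls back to 1 and SLIM
reduces to BH.

### Extraction

`get_methyl_diff()` keeps units with `qvalue < 0.01` and
`|meth.diff| > 25` percentage points by default, both inequalities
strict.  The absolute difference is thresholded and the sign is handled
by `type` ("hyper" means higher methylation than the control group);
this keeps one symmetric magnitude cutoff regardless of direction.
`diff_per_chromosome()` reports hyper/hypo percentages out of covered
units per chromosome plus a genome-wide row, and `write_bedgraph()`
exports browser tracks with the methylation difference as track value.

## Annotation

`nearest_tss()` reports signed distances, positive downstream of the TSS
(sign flipped on minus-strand TSS); ties in absolute distance resolve to
the lowest TSS coordinate, then name, so results are deterministic.
Gene-part labels use the precedence promoter > exon > intron >
intergenic, and CpG labels island > shore > other; each event therefore
receives exactly one label and category percentages always sum to 100.
Shores are the 2 kb flanks `[start-2000, start-1]` and
`[end+1, end+2000]` of each island, clipped at position 1.  Promoters
default to TSS ± 1000 bp (no universal definition exists; the extent is
configurable).  Overlap is strand-blind — a methylation event hits a
feature on either strand — and annotation results are invariant to
feature-file ordering.  Region-resolution events are matched by
any-overlap before precedence is applied.

## 5hmC adjustment

Conventional bisulfite sequencing reads 5mC + 5hmC as one protected
signal.  Given a matched 5hmC measurement, `adjust_mc_for_hmc()` applies
the level-subtraction contract: adjusted% `= max(0, mc% - hmc%)` per
base, with counts re-derived from the 5mC coverage by half-up rounding,
so coverage is conserved.  Bases missing from the 5hmC sample pass
through unchanged (counted in a message); bases covered only in the 5hmC
sample are ignored — no imputation.  Joint statistical modeling of the
paired protocols is out of scope; the adjusted methylome flows through
the differential machinery unchanged.

## The synthetic-data generator

`simulate_methylomes()` draws, per site and sample, a negative-binomial
coverage (mean 30, dispersion 8 by default — typical RRBS depth, with
P(coverage < 10) small enough that most sites survive the default
filter) and a binomial methylated count from the site's group
proportion.  The default baseline landscape is bimodal: 70% of sites
from Beta(1, 30) (nearly unmethylated), 20% from Beta(30, 1) (nearly
fully methylated), 10% uniform on [0.1, 0.9] — mirroring the
high-or-low landscape of real methylomes.  An optional clonal spike
multiplies coverage at a random subset of site/sample pairs, emulating
PCR duplication bias.  Differential signal shifts the treatment
proportion of a chosen fraction of sites by `effect_delta` points;
affected sites are drawn among sites with headroom to express the full
shift, reflecting that methylation gains concentrate where baseline
methylation is low (CpG-island hypermethylation being the canonical
case).  A `baseline = "uniform"` option places all proportions in
[0.1, 0.9]; calibration experiments use it because type-I error of an
asymptotic chi-square test is meaningfully assessed away from the
boundary, where near-constant all-zero counts would otherwise dominate.

All generators pin the RNG (Mersenne-Twister / inversion / rejection
sampling) and restore the caller's RNG state, so a seed fixes the output
across platforms and sessions.

What the generator does **not** emulate: linkage disequilibrium-like
spatial correlation of methylation along the genome, context mixtures,
bisulfite conversion failure, mapping artifacts, or between-replicate
overdispersion.  Passing tests on synthetic data therefore demonstrate
correctness of the computations under the stated generative model, not
performance guarantees on arbitrary real libraries — in particular,
binomial-only replicate variation makes the logistic test look
better-calibrated than it can be on biologically heterogeneous
replicates.

## Problem sizes and verification

The test suite builds every fixture in code at run time.  Calibration
uses 4-vs-4 designs with roughly 2 000–2 700 commonly covered units
(3 000 simulated sites before filtering) — large enough for stable
rejection-rate estimates, small enough to run in seconds; power uses
2 500 sites with a +40-point shift at 10% of sites; the Fisher
implementation is compared against exhaustive enumeration of all 245 025
2x2 tables with margins up to 30.  The same computations are re-run from
scratch by `scripts/acceptance.R`, which writes the resulting quantities
as JSON.

## Known limitations

* No beta-binomial/overdispersion model; replicate heterogeneity beyond
  binomial inflates significance.
* No de novo DMR segmentation — only fixed tiles and user regions.
* No paired-end overlap deduplication or alignment-level processing;
  the SAM reader trusts the aligner's calls.
* The SLIM $\hat\pi_0$ is a point estimate; on small unit counts SLIM
  deliberately degrades to BH rather than risk an unstable rescaling.
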