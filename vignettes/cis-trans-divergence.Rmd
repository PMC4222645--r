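---
title: "Dissecting cis and trans regulatory divergence from allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting cis and trans regulatory divergence from allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrans)
```

## The measurement model

In an F1 hybrid between a maize inbred and a teosinte inbred, the two
parental alleles of every gene sit in the same nucleus and share one
trans-acting environment. Any allelic imbalance in the hybrid therefore
reflects *cis*-acting differences only. The parent inbreds, by contrast,
express each allele in its own trans environment, so the parent expression
ratio combines cis and trans effects. Writing read counts at segregating
sites as maize:teosinte ratios,

- `cis = log2(hybrid_maize / hybrid_teosinte)`
- `cis + trans = log2(parent_maize / parent_teosinte)` (library-corrected)
- `trans = log2(parent ratio) - log2(hybrid ratio)`

Two exact binomial tests ask whether the hybrid and parent ratios deviate
from 1:1, and a Fisher's exact test asks whether the two ratios differ from
each other. The FET is only run for genes where at least one binomial test
is significant; genes with both binomial tests non-significant are
*conserved* regardless of any FET outcome. The significance pattern, plus
the relative direction of the cis and trans effects, assigns one of seven
categories:

| category | parent BT | hybrid BT | FET | directions |
|---|---|---|---|---|
| cis | sig | sig | not sig | — |
| trans | sig | not sig | sig | — |
| cis + trans | sig | sig | sig | same |
| cis x trans | sig | sig | sig | opposite |
| compensatory | not sig | sig | sig | — |
| conserved | not sig | not sig | (not run) | — |
| ambiguous | every other pattern | | | |

A zero trans direction is grouped with "same direction". Directions are
computed from the counts themselves (cross products), so genes with a zero
count on one side are still classified even though their log ratios are
undefined.

### Multiple testing

False discovery is controlled with Storey q-values at an FDR of 0.5%
(`fdr_threshold = 0.005`). The null proportion is estimated at a single
fixed `lambda = 0.5` — `pi0 = mean(p > 0.5) / 0.5`, clamped to (0, 1] with
a `1/m` floor — rather than with the usual spline smoother, so results are
exactly reproducible and have no tuning path. The three test families
(parent binomial, hybrid binomial, FET) are corrected separately, within
tissue: they test different hypotheses on different gene subsets, and
pooling them would let the heavily non-null binomial families distort the
FET's pi0. Whether to correct across tissues jointly is genuinely open; we
correct per tissue because tissues differ in gene sets and depth profiles.

### Exact tests at RNA-seq depth

Because the null is symmetric at p = 0.5, the minimum-likelihood two-sided
binomial p-value reduces to `min(1, 2 * P(X <= min(m, t)))`, which we
evaluate vectorized; the FET p-value is the direct sum of hypergeometric
probabilities not exceeding the observed table's (with the conventional
`1 + 1e-7` tie tolerance). Both agree with `stats::binom.test()` /
`stats::fisher.test()` to numerical precision — the test suite checks this
against those implementations and against independent combinatorial
enumeration — but run orders of magnitude faster at depths in the hundreds
of thousands of reads.

## Ratio assembly

Replicates are pooled by summation. Parent counts are corrected for
library-size differences by scaling the larger library *down* to the
smaller one (rounding half-to-even), never up, so the count-based tests are
not handed manufactured precision. A gene enters the analysis for a cross
only if both the hybrid and the parent comparison reach `min_depth = 100`
reads.

The overall (across-cross) hybrid ratio is a plain sum over passing
crosses. The overall parent ratio needs care because one inbred parents
many crosses: each inbred's pooled count enters once, scaled to the
smallest library among the inbreds involved, weighted by the number of
passing crosses it participates in (both sides then carry equal total
weight by construction). The two weighted sums are finally rescaled by a
common factor so that their total equals the once-counted read total: the
ratio is the weighted ratio, but the depth seen by the binomial test is the
number of distinct reads actually observed. Without that rescale the parent
total counts every read roughly "mean weight" times (about 4x in a 29-cross
panel) and the parent binomial test and FET become sharply
anti-conservative; with it, planted-category recovery in the acceptance
simulations rises from ~94% to ~100%.

Log ratios involving a zero count are left undefined (`NA`) rather than
pseudo-counted; such records keep their counts for pooled sums and tests
but drop out of effect-size summaries. A `+0.5` pseudo-count variant was
considered and rejected as a default because it biases small-count ratios
toward zero divergence.

## Candidate lists and consistency tiers

CCT genes (categories cis or cis+trans) are candidates for direct selection
on expression. Lists are restricted to genes with data from at least 15
passing F1s covering at least 3 maize and 5 teosinte inbreds, then tiered
by the depth-weighted fraction of hybrid reads agreeing in allelic
direction: tiers A / B / C at 100 / 90 / 80% consistency in either
direction. Weighting uses *hybrid* depth and the *hybrid* ratio sign —
tiers qualify the cis effect specifically, and the hybrid readout is the
clean cis signal; crosses with exactly 1:1 hybrid counts contribute depth
to the denominator only. The same machinery builds cis-only and trans-only
lists for contrast analyses.

Two bias checks accompany the lists: an exact binomial test of the
maize:teosinte split of favored alleles, and a 2x2 FET comparing bias
counts between F1s that do and do not involve the reference line (B73) — a
systematic alignment artifact would make maize bias strongest in
reference-line crosses.

## Divergence metrics, variance partition, dominance

The cis share `|cis| / (|cis| + |trans|)` is binned by total divergence
(`|log2 parent ratio|` in unit bins, 5+ open-ended), with a seeded
percentile bootstrap (default 1000 resamples of genes within bins) for 95%
intervals; the bootstrap is used because no distributional form for the
share is available. Leave-one-out influence recomputes the overall hybrid
ratio with each cross removed; exchangeable crosses give deltas peaked at
zero shrinking as O(1/n).

Per gene, a weighted least-squares model regresses the per-cross log2
hybrid ratio on maize-parent and teosinte-parent factors (weights =
per-cross hybrid depth). Each side's contribution is a drop-one (Type II)
R^2 — the increase in weighted RSS when the factor is dropped over the
total weighted SS — matching the drop-one F-tests used for significance
(p < 0.05, unadjusted). Drop-one rather than sequential attribution keeps
the two R^2 values order-invariant; in unbalanced designs they need not sum
to the model R^2. Teosinte inbreds appearing in only a single cross are
removed first (their factor level is confounded with that cross's
residual). The summary statistic is the ratio of mean R^2 values (ratio of
means, not mean of ratios, which would be dominated by small denominators),
with a delta-method or bootstrap SE. Simulations show the ratio-of-means
estimator pulls slightly toward 1 when per-factor degrees of freedom are
few (5 df per side in a 6x6 panel); planted variance ratios of 0.25 / 0.5 /
1.0 are recovered at roughly 0.32 / 0.58 / 1.02 — monotone and within 0.1.

Dominance uses library-normalized (counts per million) expression totals:
the additive effect `a = (P_M - P_T) / 2`, dominance `d = F1 - midparent`,
and `D/A = d / |a|`, so +1 means the F1 matches the higher parent
regardless of species. Per-gene D/A values across crosses pass through an
iterative Dixon outlier filter before averaging: the most extreme value is
tested with the staged Q statistic (r10 for n <= 7, r11 for 8-10, r21 for
11-13, r22 for n >= 14) against embedded two-sided alpha = 0.05 critical
values for n = 3..30 (samples beyond 30 use the n = 30 value,
conservative), and removal repeats until no rejection or only three values
remain. The staged-r variant is a deliberate choice — the classical "Dean &
Dixon" reference does not pin one — and is isolated behind `dixon_filter()`.
Classification: additive if `|D/A| < 0.25`, dominant if `0.75 < |D/A| <
1.25`, otherwise "other"; the dominant allele maps to a species via the
consensus sign of `a`.

## Enrichment

Gene-set overlaps are hypergeometric FETs with the product-formula expected
count; the tail is configurable and defaults to one-sided enrichment, since
published analyses of this kind mix one-tailed and unstated-tail tests.
The universe for each test is the set of assayed (filter-passing) genes in
the relevant tissue, or the union universe for union lists. QTL-interval
tests drop intervals with more than 20 member genes (they carry little
positional information) and Bonferroni-correct over traits. Selection-scan
score comparisons (e.g. XPCLR) use natural-log scores with a two-sample
Kolmogorov-Smirnov test for shape and a Welch t-test for the mean.
BH and Bonferroni corrections come from `stats::p.adjust()`. No gene lists
are hard-coded; all sets arrive as two-column TSVs.

## The synthetic-data generator

`simulate_design()` mirrors the structure of a domestication ASE panel: 6
maize and 9 teosinte inbreds, 29 of the 54 possible F1s (every line used at
least once), three tissues, replicate counts `1 + Poisson(0.96)` averaging
1.96. `simulate_truth()` plants each gene x tissue in one of six categories
(`ambiguous` is never planted — it exists only as a test outcome) with
effects in log2 units: magnitudes `scale * (1 + |N(0, 0.5)|)` with random
signs, so the scale parameter is a guaranteed minimum effect; compensatory
genes have `t = -c` exactly; per-line cis deviations are normal with
species-specific SDs, smaller on the maize side by default
(`sigma_cis_maize = 0.23` vs `sigma_cis_teosinte = 0.25`, echoing the
bottleneck-driven diversity deficit of roughly 0.85 in variance).

`simulate_counts()` draws, for cross (M, T) with effective cis effect
`c* = c + dev_M - dev_T`, the hybrid total depth
`N ~ NegBin(mean_depth x libsize, alpha)` (variance `mu + alpha mu^2`,
Poisson at `alpha = 0`), then the maize-allele count
`Binomial(N, 2^c* / (1 + 2^c*))` — conditioning on total depth makes the
hybrid ratio a pure cis readout, exactly the quantity the hybrid binomial
test assumes. Parent lines express only their own allele with mean
proportional to `libsize x 2^{+(c+t)/2 + dev_M}` (maize) or
`libsize x 2^{-(c+t)/2 + dev_T}` (teosinte), so the corrected parent log
ratio equals `c* + t` by construction. Library-size factors are log-normal
with mean 1 and CV `libsize_cv` per genotype x tissue x replicate. Default
`mean_depth = 300` and `dispersion = 0.05` are plausible round numbers for
allele-informative depth and biological overdispersion, not estimates of
any particular data set — no published per-gene depth distribution was
available to calibrate them.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analysis relies on: binomial
allele sampling in hybrids, overdispersed parent counts, library-size
variation, per-line allelic series with unequal species variances, and the
category structure. It does **not** simulate reads, segregating-site
placement, alignment bias, tissue-correlated effects, or — importantly —
overdispersion of the *hybrid allele split* beyond binomial. Two
consequences for interpreting green tests:

- The parent binomial test is exactly calibrated only under
  Poisson/binomial sampling. With `dispersion > 0` it is anti-conservative
  on parent counts, as it is on real data; the null-calibration acceptance
  check therefore runs at `dispersion = 0`.
- Library normalization by total counts assumes a mostly-unchanged
  transcriptome. Recovery simulations use a majority-conserved panel
  (70% conserved); with most genes strongly DE the panel-composition
  offset in the parent ratio (~0.02-0.03 log2 at 2000 genes) becomes
  detectable at high depth and erodes cis/compensatory recovery. Real
  panels of ~17k mostly-conserved genes sit well inside the safe regime,
  but this is a genuine identifiability limit of relative counts, not a
  software artifact.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `run_all()` writes
deterministic, sorted TSVs plus a manifest (package version, seed, config
hash) and reruns are byte-identical. Defaults of all thresholds live in
`run_config()` and round-trip through YAML; the 5% FDR sensitivity variant
is `run_config(fdr_threshold = 0.05)`, not a separate code path.

Simulation-based checks in the test suite use 2000-gene single-tissue
panels at depth 5000 for classifier recovery, 800-gene 6x6 full-grid panels
for variance-partition calibration, and a 500-gene three-tissue panel for
the end-to-end determinism check — sizes chosen so each check exercises the
full pipeline at meaningful statistical resolution while the whole suite
stays comfortably runnable on a laptop.
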