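---
title: "Detecting tumour copy-number alterations in plasma cfDNA bin counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumour copy-number alterations in plasma cfDNA bin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaCNA)
```

## The problem

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture: a fraction
$f$ of the fragments derive from tumour cells, the rest from normal tissue.
A region present at copy number $c$ in the tumour contributes
$1 + f\,(c-2)/2$ times the diploid read depth, so a single-copy gain at
$f = 0.10$ raises coverage by just 5%. The pipeline in this package detects
such events from low-coverage whole-genome sequencing of the kind used in
non-invasive prenatal testing (NIPT): single-end reads counted into fixed
non-overlapping 50-kb genomic bins, a few hundred reads per bin.

The stages, each its own module:

1. **Binning** — reads are assigned to bins by their 5' start position
   (single-end data, so reads, not fragments, are counted).
2. **Exclusion** — bins with high cross-panel variance-to-mean ratio,
   low mappability or high repeat content are masked.
3. **GC adjustment** — a sample-specific robust LOESS of count on GC
   fraction, rescaling each bin by `median(fitted)/fitted(gc)`.
4. **PCA smoothing** — per-bin log2 ratios of the sample's bin fractions to
   the reference-panel medians, minus their projection onto the panel's
   top-$K$ principal components ("higher-order artefact" removal).
5. **Segmentation** — circular binary segmentation (CBS) per chromosome.
6. **Classification (CADET-style)** — every segment is scored by a
   MAD-scaled z-statistic, a Gaussian log odds ratio, and a bootstrap
   confidence level; significant events larger than 10 Mb are reported,
   and whole-chromosome gains of chromosomes 13/18/21 set trisomy flags.
7. **Tumour fraction** — a ridge regression of known fraction on regional
   autosomal depth (chromosomes 13, 18, 21, X and Y excluded).
8. **Cohort summaries** — detection tables by cancer type and FIGO stage
   group, Fisher rate comparisons, Mann-Whitney U, Kaplan-Meier and
   log-rank stratification by CNA positivity.

## The statistics, precisely

**Segment fraction.** For a set of bins $S$,
$f_{obs}(S) = \sum_{b \in S} y_b \,/\, \sum_{b \in \text{autosome}} y_b$,
with $y_b$ the GC-adjusted counts and the denominator running over all
unmasked autosomal bins. The same interval is evaluated in every
reference-panel sample, giving a reference median $m_S$ (batch-specific
when at least 8 panel samples share the sample's flow cell) and a "static"
median absolute deviation $\mathrm{MAD}_S$ pooled over the whole panel.

**Z statistic.** $Z = (f_{obs} - m_S) / (1.4826\,\mathrm{MAD}_S)$. The
1.4826 consistency factor makes "3.95 MADs" behave like a Gaussian z-score,
which is how the decision threshold is phrased; it is configurable to 1.

**Log odds ratio.** Two Gaussian hypotheses with common scale
$\sigma = 1.4826\,\mathrm{MAD}_S$: the diploid null centred at $m_S$, and a
single-copy event at the estimated tumour fraction $\hat f$ centred at

$$f_{alt} = m_S\,\frac{1 \pm \hat f/2}{1 \pm m_S \hat f/2},$$

gain/loss in the upper/lower signs. The denominator renormalizes the read
budget: the event itself inflates (or deflates) the autosomal total. For
segments that are a small share of the genome it reduces to the familiar
$m_S (1 \pm \hat f / 2)$; on small test genomes, where one event can cover
most of the autosome, omitting it places the true expected fraction below
the midpoint of the hypotheses and flips the sign of the LOR on real
events, which is why the renormalized form is used. When no tumour-fraction
model is supplied, or the estimate falls below 0.01, the LOR uses a floor
of $\hat f = 0.01$ (recorded in the report) to keep the hypotheses
distinct; the LOR's sign is insensitive to moderate misestimates of
$\hat f$.

**Bootstrap confidence level (BCL).** Within-sample check that a candidate
shift is consistent along the segment: the median shift of segment bin
counts from the rest of the chromosome is removed, the baseline is pooled
with the out-of-segment bins, pseudo-segments of the same bin length are
resampled with replacement, the shift is re-applied and the segment
fraction recomputed — 1000 times. BCL is the proportion of bootstrap
fractions with $|Z| \ge 3.95$ against the panel reference. The fraction
denominator is held at the sample's observed autosomal total (the
procedure's published description leaves the denominator open; it is
dominated by out-of-segment bins either way). A segment spanning its whole
chromosome has no outside bins; its baseline is the segment itself, with a
warning.

**Decision rule.** A segment is a reported event iff
$|Z_{CBS}| \ge 3.95$, $LOR > 0$ and $BCL \ge 0.99$; gain or loss by the
sign of $Z_{CBS}$; scope is whole-chromosome when
$|Z_{CBS}| < 0.8\,|Z_{CHR}|$, where $Z_{CHR}$ is the same statistic for
the chromosome's full unmasked bin set. A segment that covers every
unmasked bin of its chromosome is whole-chromosome scope by construction:
there $Z_{CBS} \equiv Z_{CHR}$, so the 0.8 comparison can never fire, yet
the event manifestly is the chromosome. CNAs are counted only when their
genomic span exceeds 10 Mb (strict), with masked gaps inside a segment
included in the span; adjacent same-direction significant segments
separated only by masked bins are merged (and re-scored) before the size
filter so an exclusion gap cannot split one event into two sub-threshold
halves.

## Circular binary segmentation

The arc statistic for arc $(i, j]$ of a chromosome's values is the pooled
two-sample t statistic comparing the arc with its complement; the scan
maximizes it over all arcs with at least `min_width` (default 3) bins on
both sides, treating the vector circularly. Significance of a split is
assessed by permutation: `n_permutations` (default 1000) shuffles, split
when the fraction of permuted maxima at or above the observed maximum is
at most `alpha` (default 0.01); the recursion then descends into the
pieces. Two sequential shortcuts make the full-permutation test practical:
stop for futility as soon as the exceedance count can no longer reach
$p \le \alpha$ (always exact), and — only on stretches of at least 500
bins, where the $O(n^2)$ scan is expensive — stop declaring significance
after $\lceil 2/\alpha \rceil$ permutations with zero exceedances (the
sequential-boundary device used by production CBS implementations;
decision-identical except on knife-edge stretches). Short stretches run
to the full decision so small-sample splitting stays exactly
alpha-calibrated. Adjacent segments whose means
differ by less than `merge_tol` (default 0.05 log2 units) are merged.
Zero-variance splits (noiseless change-points) are scored effectively
infinite, so exact boundaries dominate any noisy arc; ties break to the
smallest $i$, then $j$, and an arc ending at the vector boundary defers to
its complement so the tie-break is exact. CBS tuning is not part of the
published method description; the defaults above are conventional and all
configurable.

## Normalization choices

The LOESS GC fit (span 0.3, degree 2, robust `family = "symmetric"`) uses
only unmasked autosomal bins and clamps prediction to the fitted GC range;
a degenerate GC range falls back to the identity with a warning. The
PCA smoothing values are per-sample median-centred: a profile's total-count
normalization constant is not an artefact direction, and centring puts the
diploid baseline at exactly zero, which is the level the ">10 Mb from
expected diploid coverage" rule is phrased against. $K = 10$ components by
default, capped at panel size minus 2. Default exclusion thresholds:
variance/mean ratio above the 99th percentile of panel bins, mappability
below 0.75, repeat fraction above 0.5 — the exclusion criteria are cited
but not numerically restated in the source method, so these are declared
defaults. chrX/chrY are normalized but flagged non-autosomal, and every
denominator that says "autosome" excludes them.

## Tumour-fraction model

Predictors are included-bin fractions (bin count over the summed included
bins, scaled to relative depth), which makes two contracts exact:
predictions are invariant to total depth, and perturbing only excluded
chromosomes (13/18/21/X/Y) cannot move the estimate. The regression is
ridge, solved in closed form through the kernel representation
$\hat\beta = X_c^\top (X_c X_c^\top + \lambda I)^{-1} y_c$ — deterministic,
and exact at the training mean. $\lambda = 1$ on the relative-depth scale
shrinks mildly (the leading data eigenvalues are two orders larger). The
published estimator's trained coefficients are proprietary and its
"various statistical modelling methods" phrasing leaves the family open;
ridge is the declared default, trained here on synthetic cohorts with
known fractions.

## What the simulator emulates — and what it does not

`sim_config()` draws negative-binomial counts with per-bin mean
$\mathrm{depth}_s \cdot g(\mathrm{gc}_b) \cdot \exp(\sum_k \lambda_k
u_{sk} v_{kb})$: a quadratic GC bias $g$ with $g(0.4) = 1$ (LOESS-
recoverable by construction), smooth low-rank batch artefacts with
per-sample scores, lognormal depth variation (CV 10%), and overdispersion
$\mathrm{Var} = m + \phi m^2$. Tumour events multiply means by
$1 + f\,w_b (c_b - 2)/2$ with partial-bin overlap weights $w_b$ — the
unique linear two-population mixture consistent with a diploid background.

Defaults are the study conditions used throughout the tests: 50-kb bins,
500 reads per bin, a 20-sample reference panel. $\phi = 0.004$ gives
variance/mean = 3 at that depth, the mild residual overdispersion typical
of GC-corrected low-coverage bin counts. Artefact scales are 1% and 0.5%
of depth (RMS): residual higher-order structure after GC correction in a
homogeneous batch is sub-percent in practice, and a 20-sample panel's PCA
can only resolve components above the spiked-covariance detection edge —
artefacts far above that level would defeat any panel this size, which is
inconsistent with the demonstrated sensitivity of the platform being
emulated (whole-genome CNA detection around 10% tumour fraction).
Normalization tests that specifically exercise artefact removal plant much
larger components (30%/20%) with the noise turned down.

The simulator does not model fragment lengths (the detection method uses
none, though fragment-size differences between tumour and background cfDNA
motivate the platform), sequencing error, mappability-driven coverage dips
(annotations are inputs), or genuine biological copy-number polymorphism
in the panel. Passing the simulation suite therefore demonstrates correct
statistics and recovery under the stated noise model, not performance on
real plasma libraries.

A scale caveat worth knowing: on the 150-Mb two-chromosome test genome a
100-Mb event is two-thirds of the autosome, so it measurably depresses the
*other* chromosome's fraction (the read budget is closed) and the pipeline
can report a complementary whole-chromosome loss there. At hg19 scale the
same event is 3.5% of the autosome and the effect is negligible. The
sensitivity checks therefore assert recovery of the true event rather than
the absence of spillover calls.

## Numerical and degenerate-input choices

Bootstrap and permutation RNG streams are seeded deterministically from
the run seed plus segment/stretch coordinates, so per-segment results do
not depend on processing order and whole runs are bit-reproducible. A
segment reference MAD of zero falls back to a per-bin pooled MAD
(root-sum-square), with a warning. Constant vectors segment to a single
segment with $T = 0$. The cohort detection rates are rounded half-up to
one decimal, matching clinical-table presentation (banker's rounding would
print 41.6 where the table prints 41.7). Stage groups are fixed as I–II
early, III–IV advanced. The rate-comparison test is Fisher's exact
(two-sided, hypergeometric tail sum) with chi-square as an option — the
source analysis does not name its test, and the package does not attempt
to reproduce that p-value exactly. Mann-Whitney U uses midranks,
enumerating all label assignments exactly (ties included) when
$n_1 + n_2 \le 12$ and the tie-corrected normal approximation otherwise.

## Problem sizes in the checks

The bundled validation uses the 3000-bin toy genome with a panel of 20:
null specificity and spike-in sensitivity run 20 seeded replicates each;
CBS is cross-checked against exhaustive oracles on vectors up to length
50; the tumour-fraction model trains on 100 simulated samples with
$f \sim U(0, 0.3)$ and is scored on 20 held-out samples; log-rank
calibration uses 500 uncensored two-arm replicates of $n = 30$ each.
These sizes were chosen so the whole suite runs on a laptop in minutes
while keeping every stochastic bound several standard errors away from
its threshold.

## Known limitations

- Per-patient survival data for the clinical cohort were never published;
  the survival stack is validated on exact hand-computed examples,
  calibration simulations, and the synthetic cohort only.
- The cohort summary table in the source publication contains two
  internal inconsistencies (an early-stage endometrial rate printed as
  19.5% where its own counts give 12.2%, and one group median that does
  not equal the median of the listed per-sample sizes); the package
  reproduces the arithmetic implied by the counts.
- chrX handling is generic (no female-panel special-casing beyond what the
  supplied panel contains); chrY is excluded from autosomal denominators.
- Segment references are the exact bin interval across the panel, the most
  literal reading of "median segment fraction of the reference
  distribution"; alternatives (e.g. per-bin references aggregated) would
  shift borderline z-scores slightly.
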