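---
title: "Modelling memory-like responses to repeated cytokine stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling memory-like responses to repeated cytokine stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restim)
```

## The experimental design

`restim` analyses *two-hit* stimulation experiments. Cells from each donor are
split into four arms: an untouched control (`CTRL1`); a single acute
stimulation, harvested a few hours later (`HIT1`); a stimulated-then-rested
arm that controls for the history of the first exposure (`CTRL2`); and a
restimulation after the rest (`HIT2`). The scientific question is whether the
first exposure leaves a mark — enhanced re-responses (training), a sustained
elevated state (priming), or a dampened re-response (tolerance) — in gene
expression and in chromatin accessibility.

Because every donor contributes all four conditions, donor is a blocking
factor: inter-individual baseline differences are large in primary cells, and
the paired layout lets the model absorb them instead of paying for them in
the error term.

## The count model and the five contrasts

For each feature (gene or accessibility peak) with counts \(y_{ds}\) for donor
\(d\) and condition \(c(s)\) of sample \(s\), we fit a log-link
negative-binomial GLM

\[
y_{s} \sim \mathrm{NB}(\mu_s, \alpha), \qquad
\log \mu_s = \log f_s + \delta_{d(s)} + \beta_{c(s)},
\]

with sample size factor \(f_s\) (median-of-ratios), donor effects
\(\delta_d\), condition effects \(\beta_c\) (reference `CTRL1`), and the NB
variance \( \mu + \alpha\mu^2 \). Fitting is by iteratively reweighted least
squares with fixed \(\alpha\), weights \(\mu/(1+\alpha\mu)\); the coefficient
covariance is the inverse expected information. The unit tests pin the fitted
coefficients against an independent fixed-dispersion GLM implementation to
better than \(10^{-6}\) relative error.

Five Wald contrasts of the condition effects are tested per feature:

| name | contrast | question |
|---|---|---|
| `HIT1vCTRL1` | \(\beta_{H1}\) | acute response to a single hit |
| `HIT2vCTRL2` | \(\beta_{H2}-\beta_{C2}\) | response to restimulation over its own baseline |
| `HIT2vHIT1` | \(\beta_{H2}-\beta_{H1}\) | direct single-vs-repeat comparison |
| `CTRL2vCTRL1` | \(\beta_{C2}\) | residual state change after stimulation and rest |
| `INTERACTION` | \((\beta_{H2}-\beta_{C2})-\beta_{H1}\) | baseline-controlled change in responsiveness |

P-values use the two-sided normal reference (the convention of standard
NB differential-expression tools) and are Benjamini–Hochberg adjusted within
each contrast across all features. A feature is *significant* in a contrast
when `padj <= 0.05` and `|log2FC| >= 0.5`; both thresholds are configurable
(`restim_config()`). Features are pre-filtered to those with a count of at
least 20 in at least 3 samples. Non-converged or singular fits are flagged
and assigned `p = 1` so the BH denominator stays stable.

## Dispersion estimation

With 20 samples and 8 model parameters there are only 12 residual degrees of
freedom per feature, so fully per-feature dispersion estimation is noisy and
any systematic bias propagates straight into test calibration. The estimator
used here:

1. fits a Poisson GLM (donor + condition, offset) per feature; features whose
   Pearson chi-square does not exceed the residual df get the floor
   \(\alpha_{\min} = 10^{-8}\);
2. otherwise solves for \(\alpha\) such that the NB Pearson chi-square of the
   refitted model matches the residual df (a fixed-point iteration
   \(\alpha \leftarrow \alpha \cdot X^2(\alpha)/(n-p)\));
3. blends the per-feature estimates on the log scale toward a pooled trend —
   the common dispersion that makes the *total* Pearson chi-square across
   features match the total df — with weight 0.8.

Two deliberate choices deserve a note. First, the model residuals (not raw
within-condition moments) define the dispersion: the donor effect is shared
across features, and leaving it in the variance would roughly double the
apparent dispersion at these settings and make the paired Wald test strongly
conservative — defeating the purpose of the paired design. Second, the strong
blend reflects the 12-df reality: the pooled trend is nearly noise-free,
per-feature estimates are right-skewed with a low median, and an unshrunk
plug-in noticeably inflates type-I error. The all-null calibration suite
(2 000 simulated genes) checks that per-contrast raw p-values stay within a
Kolmogorov–Smirnov distance of 0.05 from uniform and that the fraction below
0.05 stays in \([0.03, 0.07]\).

## Memory classification from contrasts

`classify_memory()` turns the five significance flags into one call per gene
with a fixed precedence: interaction-positive is `TRAINED`,
interaction-negative `TOLERIZED`; then `PERSISTENT` (significant in
`CTRL2vCTRL1` and `HIT2vHIT1` with the same sign), `PRIMED` (significant in
`CTRL2vCTRL1` and `HIT2vCTRL2`), `TRANSIENT` (significant in `HIT1vCTRL1`
only), else `NONRESPONSIVE`.

One consequence is worth understanding before interpreting the calls. A gene
that rises with the first hit and simply *stays* elevated (the persistent
trajectory `1,4,4,4`) has a genuinely negative baseline-controlled
interaction — it does not respond a second time on top of its elevated
baseline — and precedence assigns it `TOLERIZED`. The same happens to the
classic primed shape `1,4,2,4` (interaction \(-1\) in log2). This is not a
defect: the interaction contrast measures *responsiveness change*, and from
that vantage point a persistent state *is* a dampened re-response. The
trajectory-clustering view below is the complementary lens that separates
sustained elevation from genuine tolerance; the two tables should be read
together.

## Trajectory clustering

`condition_profiles()` computes, per gene, the mean of
\(\log_2(\text{normalized count}+1)\) per condition across donors, z-scored
across the four conditions (profiles with zero spread are flagged flat and
excluded). `cluster_trajectories()` uses the correlation distance
\(1-r\) between z-profiles with average-linkage hierarchical clustering,
cuts the tree at a fixed height, dissolves clusters below 15 genes, and
labels each surviving cluster with the archetype of its mean profile via a
dead-zone rule table on the deltas \(d_1 = \mathrm{HIT1}-\mathrm{CTRL1}\),
\(d_2 = \mathrm{CTRL2}-\mathrm{CTRL1}\), \(d_3 = \mathrm{HIT2}-\mathrm{CTRL2}\)
(`label_archetype()`, \(\varepsilon = 0.25\) z-units).

The cut height deserves its own paragraph. With only four conditions,
correlation distances between *distinct* upward trajectory shapes are tiny —
the transient (`1,4,1,4`) and trained (`1,4,1,8`) templates sit at
\(1-r \approx 0.04\) from each other — so any cut much above that merges all
upward responders into a single blob. For profiles
\(\text{template} + \mathcal{N}(0,\sigma^2)\) the expected within-archetype
distance is \(\approx 2\sigma^2/s^2\), where \(s\) is the template's spread
across conditions. At this package's study conditions the condition-mean
noise is \(\sigma \approx 0.2\) log2-units (five donors, dispersion 0.1) and
typical template spreads are \(s \approx 1.2{-}1.5\), giving \(\approx
0.05\) — the default `cut_height`. It remains a knob: lower it for
lower-noise data, raise it to merge fine shape distinctions. The recovery
suite plants the eight archetype templates at this noise level and requires
an adjusted Rand index of at least 0.8 over the responsive archetypes. The
flat (non-responsive) archetype is excluded from that score on purpose: its
z-profile is amplified pure noise, and in the real pipeline non-responsive
genes never reach the clustering stage (only differentially expressed genes
are clustered).

## Chromatin: consensus peaks, DOR categories, gene mapping

Per-sample peak calls (BED, 0-based half-open) are merged into maximal
connected regions; a region's *support* is the number of distinct samples
contributing at least one overlapping base, and regions with support below
`min_consensus_support` (default 5) are discarded. Support counting is
region-level, matching the "present in at least N replicates" reading, and
the merge is idempotent. The unit suite checks merged bounds and supports
against a base-resolution brute-force counter on random instances.

Differential accessibility reuses the same NB engine on the peak count
matrix. Peaks significant in both direct-stimulation contrasts
(`HIT1vCTRL1`, `HIT2vCTRL2`) are *shared* differential open regions (DORs);
peaks significant in exactly one are *dynamic* (the symmetric difference).
Summary percentages use `pct()`, integer rounding half away from zero.

Peaks are annotated to feature classes with HOMER-style strand-oriented
windows — promoter \([-1\,\mathrm{kb}, +100\,\mathrm{bp}]\) around the TSS,
the mirrored window at the TTS, gene body, else intergenic, first match in
that precedence — and mapped to genes whose TSS lies within a
\(\pm 10\) kb window (`map_dor_to_genes()`).

## SNP enrichment by matched-background permutation

The statistic is the number of target peaks containing at least one catalog
SNP (a peak counts once however many SNPs it holds; a total-SNP variant is
available via `stat = "snps"`). A SNP at 1-based position \(p\) is inside the
0-based half-open peak \([s,e)\) iff \(s < p \le e\). The null distribution
draws, for each permutation, a background peak set matched to the target's
composition over strata of width quintiles crossed with feature class;
sampling is uniform without replacement within each stratum (falling back,
with a warning, to replacement if a stratum is exhausted — `auto_strata()`
picks the finest matching scheme the background can actually support). The
empirical p-value uses the add-one convention
\(p = (1 + \#\{ \text{null} \ge \text{obs}\})/(n_{\text{perm}}+1)\),
one-sided upper tail, so it is never zero; the enrichment score is
observed/mean(null). No multiplicity adjustment is applied across trait
categories by default (a BH option exists).

A practical caveat the calibration suite encodes: because null sets are drawn
from the background *only* (not from target ∪ background), the null variance
carries a finite-population correction of roughly \(1 - k/N_b\). When the
background is only a few times larger than the target this understates the
null spread and inflates rejections; with background-to-target ratios around
ten — typical for differential regions against a consensus peak universe —
the test is calibrated (null rejection rate within \([0.03, 0.07]\) at
\(\alpha = 0.05\) over 400 seeded runs). For small backgrounds, prefer
interpreting the enrichment score over the p-value.

## The synthetic-data generator

The generator is first-class, tested code, and defines the package's study
conditions: 5 donors × 4 conditions per stimulus; NB counts with dispersion
\(\alpha = 0.1\); a gene-shared donor effect, \(\exp(\mathcal{N}(0, 0.3))\);
library size factors uniform in \([0.7, 1.3]\); eight trajectory archetypes
with multiplier templates over (CTRL1, HIT1, CTRL2, HIT2) — non-responsive
(1,1,1,1), transient (1,4,1,4), primed (1,4,2,4), trained (1,4,1,8),
tolerized (1,4,1,1.5), persistent (1,4,4,4), delayed (1,1,4,1), suppressed
(1,0.25,1,0.25) — with baseline expression log-normal (median 200). Peaks are
placed without overlap on a 2 × 10 Mb synthetic genome with log-normal widths
(median 500 bp, \(\sigma = 0.5\)); every true consensus peak appears in at
least 5 per-sample BED sets with ±25 bp edge jitter, decoys in fewer. SNP
catalogs are Poisson per peak (density × width), with an optional planted
density fold in a target class; `planted_fold = 1` is the null.

What the generator does *not* emulate: read-level artifacts (no FASTQ, GC or
fragment-length bias), correlated gene programs (genes are independent given
the donor effect), linkage structure among SNPs, overlapping or nested peak
architectures, and outlier samples. Passing recovery tests on this generator
therefore demonstrates that the estimators and decision rules are correct and
calibrated under the stated model — not that they are robust to everything
real sequencing data can do.

## Numerical and design choices

* IRLS: coefficient-change tolerance \(10^{-10}\) (tightened to \(10^{-13}\)
  in oracle comparisons), max 100 iterations, linear predictor clamped to
  \(\pm 30\); singular information or NA coefficients flag the feature.
* Size factors: features with a zero anywhere are excluded from the geometric
  means; if none remains, total-count scaling with a warning.
* `pct()` rounds half away from zero — 52 of 113 prints as 46%, 61 of 113 as
  54%.
* Cluster ids are assigned by decreasing cluster size with ties broken by the
  lexicographically smallest member gene id; genes are processed in sorted
  order, so assignments are order-independent.
* Per-stage seeds derive from one global seed via a stage-name hash
  (`stage_seed()`), so any stage can be reproduced in isolation and two runs
  with the same seed are checksum-identical (the report contains no
  timestamps).
* Test problem sizes: 2 000 genes for calibration, 500 genes per planted
  class for recovery, 3 500 profiles for clustering recovery, 200 random
  instances for the consensus oracle, 400 + 100 runs at 200 permutations for
  the permutation suites. These sizes give Monte-Carlo standard errors an
  order of magnitude below the tested margins.

## Known limitations

* At the default study conditions the baseline-controlled interaction for the
  trained template (log2 interaction of 1) sits near \(z \approx 2.45\),
  so contrast-based trained recall plateaus in the low 0.6s; the
  trajectory-clustering pathway separates the same shapes much more reliably.
  Detecting subtler training effects needs more donors.
* Dispersion outliers are shrunk hard toward the trend (weight 0.8); data
  with genuinely heavy-tailed per-feature dispersion (e.g. contaminated
  samples) would be better served by a lower blend.
* The Wald/normal reference is mildly anti-conservative at 12 residual df
  (the all-null significant fraction sits slightly above 0.05); this matches
  the conventions of the field's standard tools rather than a t-reference.
* The permutation null requires an adequately large background set (see
  above); the pipeline refuses to test target sets the background cannot
  match stratum-by-stratum.
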