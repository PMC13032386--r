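---
title: "Methods: filtering, left-censored imputation and subtype signatures in myofiber proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, left-censored imputation and subtype signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberomics)
```

# The analysis problem

Laser-capture microdissection mass spectrometry (LCM-MS) profiles the
proteome of microscopically selected myofibers. In inflammatory muscle
disease this makes it possible to compare pathologically-associated
fiber subtypes — regenerating fibers positive for embryonic myosin
(eMyH-F), centrally nucleated fibers (CN-F), and fibers adjacent to
inflammatory infiltrates (Inf-F) — against control fibers, at the
resolution of single fiber populations rather than bulk biopsy lysate.

The data are a protein-group intensity matrix (proteins × samples, as
exported by a DIA search engine) in which missingness is heavily
*left-censored*: low-abundance proteins fall below the detection limit,
so the probability of observing a value rises with intensity
(missing-not-at-random, MNAR). Because captured material per sample is
tiny, the matrices are also noisy and sparse, and the design is small:
a few donors per condition, each fiber subtype captured in triplicate.
Every stage of this package exists to make that data structure
analyzable and, critically, *testable*: a synthetic-data generator
reproduces the statistical structure the analysis assumes, so each
stage can be validated against ground truth.

# Pipeline overview

1. **Ingestion** (`read_protein_matrix()`, `exclude_contaminants()`,
   `qc_exclude_low_depth()`): parse the wide TSV, encode missingness
   explicitly (`NA`, never 0), drop rows whose accession carries the
   contaminant prefix (`"contam"`), and exclude samples whose
   detected-protein count falls below half the median sample depth.
2. **Missingness filters** (`filter_replicate_support()`,
   `filter_donor_support()`): Filter 1 blanks a protein's counts within
   a (donor, subtype) triplicate when detected in fewer than 2
   replicates; Filter 2 blanks a protein from a whole subtype when
   fewer than 2 donors detect it there. Condition-level contrasts run
   on the Filter-1 dataset; subtype signatures on Filter 1+2.
3. **Imputation** (`fit_qrilc()`, `impute_qrilc()`): QRILC —
   per-sample estimation of the complete intensity distribution from
   the observed upper tail, followed by truncated-normal draws for the
   censored lower tail.
4. **Normalization and averaging** (`median_normalize()`,
   `average_replicates()`): per-sample median subtraction on the log2
   scale, then arithmetic means over each (donor, subtype) triplicate.
   All group comparisons run on the averaged columns.
5. **Testing** (`ttest_condition()`, `anova_subtypes()`,
   `ratio_contrast()`, `pca_summary()`): row-wise pooled-variance
   t-tests between conditions and additive two-way ANOVA
   (subtype + donor) among fiber subtypes, both corrected with the
   Benjamini–Yekutieli (BY) step-up procedure.
6. **Signatures and annotation** (`signature_patterns()`,
   `venn_counts()`, `zscore_matrix()`, `annotate_signatures()`,
   `category_contrasts()`, `cross_study_overlap()`): presence–absence
   classification of significant proteins over subtypes, gene-set
   mapping with Benjamini–Hochberg (BH) correction inside each set,
   and direction-aware multi-study overlap.

# The QRILC model

For sample $j$ let $p_{NA}$ be its missing fraction. QRILC assumes the
complete log2 intensities are $N(\mu_j, \sigma_j^2)$ and that the
observed values are the upper $(1 - p_{NA})$ tail. Empirical quantiles
of the observed values at probabilities $0, \ldots, q_{up}$ (grid of
100 points, $q_{up} = 0.99$) are regressed by ordinary least squares on
standard-normal quantiles spanning $[p_{NA}, q_{up}]$; the intercept
and slope are $\hat\mu_j$ and $\hat\sigma_j$. The censoring threshold
is $\Phi^{-1}(p_{NA}; \hat\mu_j, \hat\sigma_j)$, and each missing cell
is replaced by a draw from $N(\hat\mu_j, (\texttt{tune\_sigma}\cdot
\hat\sigma_j)^2)$ truncated *above* at that threshold.

Numerical choices:

* The grid top $q_{up} = 0.99$ discards the extreme upper tail, which
  is dominated by a handful of very abundant proteins.
* When $p_{NA} = 0$ the first theoretical quantile is
  $\Phi^{-1}(0) = -\infty$; non-finite grid pairs are dropped before
  the regression, so a complete column reduces to an ordinary normal
  QQ regression and recovers the sample mean and SD.
* Truncated-normal draws use the inverse CDF restricted to the
  truncation region ($u \sim U(0, \Phi(T))$, $x = \Phi^{-1}(u)$).
  This is exact, vectorized and reproducible under a seed, unlike
  rejection or Gibbs sampling.
* Degenerate columns (constant observed values, $\hat\sigma \le 0$, or
  $p_{NA} \ge q_{up}$) raise errors rather than returning a fit; a fit
  needs at least 30 observed values.

The estimator is validated two ways: against the generating truth of
left-censored normal columns (`simulate_censored_column()`), and
against an independent maximum-likelihood fit of the censored normal
on the same draws. Under the test conditions (n = 5000, 10–40%
censoring) the median absolute errors of $\hat\mu$ and $\hat\sigma$
stay within a tenth of $\sigma$ and within $0.05\sigma$ of the ML
oracle.

# Multiple-testing conventions

Both FDR procedures are step-up:
$q_{(i)} = \min_{j \ge i}\min\{1, p_{(j)} m\, c(m)/j\}$ with
$c(m) = \sum_{i=1}^m 1/i$ for BY and $c(m) = 1$ for BH. BY is used for
the proteome-wide contrasts because its validity does not depend on
the dependence structure between co-regulated proteins; BH is used
*within* gene-set contrasts (`category_contrasts()`), matching the
convention of correcting within the category being examined. The
wrappers call `stats::p.adjust`; the test suite checks them against a
naive from-the-definition step-up implementation to 1e-12.

Degenerate-row conventions: zero pooled variance with equal group
means gives $t = 0, p = 1$; a flat protein in the ANOVA gives
$F = 0, p = 1$. Proteins detected in only one condition
(pre-imputation) are reported with a uniqueness class rather than a
pseudo-infinite fold change; their fold change comes from imputed
values and is interpretable only as a floor.

# The synthetic-data generator

`simulate_dataset()` generates log2 intensities additively — protein
baseline $N(22, 3^2)$, condition effect $\pm 1.5$ for a fraction
`frac_de = 0.1` of proteins, per-donor effects $N(0, 0.3^2)$, replicate
noise $N(0, 0.5^2)$ (all in log2 units) — and exports $2^x$ on the raw
scale, as search engines do. Detection is Bernoulli with probability
$\mathrm{logit}^{-1}(\alpha + \beta x)$; the defaults
$\beta = 2.5, \alpha = -42.5$ put the detection midpoint at log2
intensity 17 (≈1.7 SD below the median abundance), so detection is
essentially complete above the median and falls steeply over the
lowest-abundance quintile — the profile of a *filtered* protein-group
matrix, and the monotone detection-vs-intensity relation that
justifies left-censored imputation. A fraction
`frac_subtype_unique = 0.1` of proteins is structurally absent from a
random strict subset of the disease subtypes, creating true
presence–absence signatures; contaminant rows carry the `"contam sp|"`
prefix; a designated sample's detection probability can be multiplied
by `low_depth_factor = 0.3` to emulate a failed acquisition.

The default design mirrors a three-donor disease cohort with three
fiber subtypes and a two-donor control cohort with two fiber size
classes, all in triplicate (39 samples); with the low-depth sample
excluded, replicate averaging yields 13 analysis columns. The
control-donor count is a free choice (two), made once; it is
configurable.

What the generator does **not** emulate: peptide-to-protein roll-up,
shared-peptide ambiguity, retention-time or ion-mobility structure,
intensity-dependent *variance* (noise SD is constant on the log
scale), batch effects, and correlated protein modules. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative assumptions, not robustness to everything real data can do.

# Statistical design choices

* **Imputation on the log2 scale.** The Gaussian censored model is
  only sensible after the log transform; the pipeline therefore runs
  log2 → impute → normalize → average. The no-imputation passthrough
  (`impute = FALSE`) is the only alternative family offered.
* **Filter 2's "detected in a donor"** means ≥1 surviving replicate
  after Filter 1 — the weakest reading consistent with the rule, so it
  removes as little signal as possible.
* **Per-sample median normalization** is the default because it is the
  only reading that equalizes loading across samples; a global-median
  variant is available for centering without changing between-sample
  offsets.
* **Two-way ANOVA factors** are subtype + donor (additive, no
  interaction): with 3 donors × 3 subtypes of averaged values this
  leaves 4 residual degrees of freedom, and the donor term absorbs the
  dominant nuisance variance. A one-way variant is used for
  per-gene-set contrasts and dot-plot style panels. Because every
  protein shares one design, the models are solved once by QR
  decomposition of the design matrix and applied to all rows;
  `lm()`/`aov()` on individual proteins serve as the oracle in tests.
* **Signature groups are presence patterns, not clusters.** The
  detected-subtype subset of each ANOVA-significant protein is
  reproducible under reanalysis, whereas heatmap cluster assignments
  depend on metric, linkage and tie-breaking. The heatmap ordering
  itself (Euclidean distance, average linkage) is provided for export
  only. The all-three pattern is retained as a seventh label alongside
  the three unique and three pairwise groups. Row z-scores use the
  population-SD convention (denominator $n$), which maps a row exactly
  onto standard-normal quantile positions.
* **Gene symbols join gene sets** (uppercase, trimmed); accession-level
  alias resolution is the user's responsibility via their input lists.
  Cross-study overlap is direction-aware by default and silently drops
  a study from a direction it does not report, rather than counting an
  empty set.

# Problem sizes and reproducibility

The test suite validates the filters against brute-force recounts on
200 random 50-protein fixtures, FDR adjustment against the naive
step-up on 1000 random vectors, QRILC on 20 censored columns of
n = 5000, null calibration and truth recovery on 5000-protein
simulated datasets (20 and 3 seeds respectively), and set algebra on
500 random fixtures per operation. These sizes were chosen so the
whole suite completes in about a minute while keeping binomial noise
well below the asserted tolerances. All randomness is seeded; a given
configuration reproduces bit-identical matrices, imputations and
q-values.

# Known limitations

* QRILC is a single-imputation method: imputed values are drawn from
  the *sample-wide* lower tail, so a sporadically missing cell of a
  high-abundance protein is replaced far below its true value. This
  inflates within-group variance for partially observed proteins and
  is the dominant cost of the method; the replicate-support filter and
  replicate averaging reduce, but do not remove, it. The acceptance
  script's `de_recovery_pct` quantifies the consequence for power
  under the default MNAR conditions; proteins observed in most cells
  are essentially unaffected.
* With two control donors the donor-support rule degenerates gracefully
  but leaves control subtypes fragile to a single failed donor.
* The BY correction is deliberately conservative; under the null it
  declares essentially nothing significant, and its power cost
  relative to BH is the price of dependence-free validity.
* Fold changes of uniqueness-class proteins are imputation floors, not
  measurements.
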