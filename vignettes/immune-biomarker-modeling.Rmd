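---
title: "Predictive immune biomarker modeling in small tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive immune biomarker modeling in small tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomark)
```

## The problem

Targeted immune profiling of tumor tissue produces, for each sample, a small
panel of analytes: transcript abundances (TPM) for co-inhibitory and
co-stimulatory receptor genes and immune-escape genes, and deconvolved
infiltration percentages for a handful of immune cell subsets. In a clinical
cohort stratified by outcome — here progression-free survival (PFS) after
front-line chemotherapy in high grade serous ovarian cancer, with groups
*long*, *intermediate* and *short* — the analysis questions are: which single
analytes separate the long from the short group, whether a small multi-analyte
classifier does better, whether analytes trend monotonically across the three
ordered groups, how analytes correlate with each other and with cell
infiltration, and whether expression stratifies survival in a larger registry
cohort.

The cohorts involved are tiny (tens of samples), so every classification
metric in this package is computed by leave-one-out (LOO) cross-validation:
each sample is predicted by a model fit to the other n − 1, and the n held-out
predictions are pooled into a single confusion matrix. "Long" PFS is the
positive class everywhere.

## Single-analyte threshold biomarkers

`fit_threshold()` enumerates every candidate cutoff (midpoints of consecutive
distinct values) in both orientations and keeps the one maximizing
sensitivity + specificity — the Youden criterion, which is what "jointly
optimizing specificity and sensitivity" is taken to mean here; the criterion
is deliberately insensitive to the 11-vs-8 class imbalance, unlike raw
accuracy. "Jointly optimizes" admits other readings (e.g. maximizing the
minimum of the two rates); the sum was chosen because it is the standard
single-number compromise and is piecewise-constant on the same candidate set.
Remaining ties are resolved deterministically: higher accuracy, then the
smaller threshold, then the high-is-positive orientation.

`analyte_table()` reports, per analyte, the group medians, the threshold fit
on the *full* long + short data (the number a report prints), the two-sided
rank-sum p-value for the group difference, and LOO metrics. Two conventions
matter:

* **Rounding.** Percentages are displayed rounded half-away-from-zero
  (89.47 → 89, 85.5 → 86); full precision is kept internally.
* **Undefined metrics.** A zero-denominator metric (e.g. PPV when nothing is
  called positive) is `NA`, rendered `-`, never imputed.

The per-analyte p-value uses the two-sided Wilcoxon rank-sum test, exact
(full enumeration) when the pooled n is at most 25 with no ties, otherwise the
tie-corrected normal approximation with continuity correction. The choice of
the rank-sum test for the per-analyte column is itself a design decision: it
is the only two-group location test the analysis protocol names, and TPM
distributions are skewed enough that a rank test is the defensible default.

## The multidimensional biomarker

The multidimensional classifier is built in three deterministic stages:

1. **Ranking** (`rank_analytes()`): analytes sorted by single-analyte LOO
   accuracy (descending), then p-value (ascending); the top 5 become
   candidates.
2. **Subset search** (`powerset_select()`): all 31 non-empty subsets of the
   candidates are evaluated by LOO misclassification count using a random
   forest with default hyperparameters (500 trees, `floor(sqrt(p))` features
   per split, minimum leaf 1, unlimited depth, bootstrap on). Lowest error
   wins; ties prefer the larger subset, then the subset whose analytes rank
   higher. The tie-toward-more-analytes rule is the stated protocol; the
   rank-lexicographic last resort merely makes the result reproducible.
3. **Grid search** (`grid_search()`): on the chosen subset, an exhaustive
   grid — trees ∈ {100, 500, 1000} × features-per-split ∈ {1..p} × minimum
   leaf ∈ {1, 2, 3} × depth ∈ {unlimited, 2, 3} — is scored the same way; the
   earliest grid point attaining the minimum is kept. The final forest is
   refit on all samples, but the *reported* per-sample scores and the
   confusion matrix come from the held-out fold predictions of the winning
   grid point, so performance is never read off resubstitution.

The per-sample score is `s = P(short) − P(long)`, the difference of the
forest's class-vote fractions, so `s ∈ [−1, 1]` with decision threshold 0
(a split vote goes to "short"). The sign convention puts the long-PFS group
at negative scores, matching the reported group medians of −0.7 (long) and
0.6 (short) for such a classifier. The scale of the published
"multidimensional value" is undocumented; the vote-fraction difference is the
natural forest-native quantity with the right range and threshold.

Randomness is controlled by one master seed; fold i of any LOO loop uses
`seed + i`, so runs are bit-reproducible. Depth limits are enforced as a cap
of `2^depth` terminal nodes, the closest control the forest implementation
exposes.

An open question in the protocol is whether the subset search is itself
re-run inside each evaluation fold (fully nested cross-validation). The
stated order — select the subset, tune, then evaluate the left-out
predictions — is implemented literally. The resulting metrics are therefore
mildly optimistic, a caveat that applies equally to the original analysis.

## Trend, correlation and comparison statistics

`cuzick_trend()` implements the Wilcoxon-type trend test across k ordered
groups: with midranks \(R_i\) and integer group scores \(l_j\) (short = 1,
intermediate = 2, long = 3), \(T = \sum l_{g_i} R_i\) is standardized by its
exact permutation moments, with the usual tie correction
\(1 - \sum(t^3 - t)/(N^3 - N)\) applied to the variance, and referred to the
standard normal, two-sided (the protocol does not state sidedness; two-sided
is the conservative default). Degenerate data (zero variance) return z = 0,
p = 1. With two groups the statistic reduces exactly to the rank-sum normal
deviate, which the tests exploit as a cross-check.

`spearman_corr()` is Pearson on midranks with the t-approximation p-value
\(t = r\sqrt{(n-2)/(1-r^2)}\) for all n — both relevant cohort sizes (26 and
378) are far beyond exact-table range. `two_sample_t()` uses the classical
pooled-variance statistic unpaired and difference scores paired, with an
explicit zero-variance contract (equal means → p = 1; unequal → limiting 0,
flagged). `fold_change()` is a ratio of arithmetic means ("mean expression"),
with medians behind a flag. `median_split()` assigns values equal to the
median alternately to the smaller side so group sizes differ by at most one.

## Survival analysis

Kaplan–Meier estimation and the log-rank test are delegated to the standard
survival machinery; the hazard ratio is the Mantel–Haenszel
observed/expected estimator \((O_a/E_a)/(O_b/E_b)\) with
\(\mathrm{CI}_{95} = \exp(\ln HR \pm 1.96\sqrt{1/E_a + 1/E_b})\), **not** a
Cox fit — the analysis pairs HRs directly with the log-rank test and fits no
regression model. `quartile_groups()` sizes the top/bottom expression arms as
n/4 rounded half up (378 → 95 per arm) with stable tie handling. A recorded
survival of 0 months is retained with a warning (one real patient record has
PFS 0). A `+` suffix in a survival field always means censoring at the
recorded time; summary *medians*, however, treat censored values as plain
numbers, because that is how the clinical summary table computes its printed
medians.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage is testable without any data
download. Its defaults are the study conditions:

* **Group sizes** 11 long / 8 short / 7 intermediate.
* **Measurement precision**: generated values are rounded to 3 decimals, the
  precision a shipped TPM/percentage table carries; write/read round-trips
  are then exact.
* **Gene TPM** is log-normal, `exp(log_mean + group_effect + log_sd · Z)`.
  The bundled panel spans five orders of magnitude across analytes, so a
  log-scale location family is the only reasonable choice. The default
  `log_sd = 0.6` gives within-group spreads (roughly 3-fold between quartiles)
  typical of bulk expression panels. Panel log-means are centered between the
  published long/short group medians so simulated medians land near the
  printed ones (intermediate sits at the center).
* **Correlated blocks** are drawn through a Gaussian copula; the latent
  normal correlation is set to `2 sin(π ρ / 6)` so the *Spearman* correlation
  hits the target ρ. The default panel plants one block — ICOS with CTLA-4 at
  ρ = 0.89 — emulating the strong observed co-expression of that pair.
* **Cell percentages** are compositional: log-normal weights per subset,
  renormalized per sample to a total immune fraction drawn as
  N(17, 2.5²) percent (clamped to [1, 60]), emulating totals of ~15–20%.
* **Survival** is exponential per group, with rates matched to the group
  median PFS values (76, 24 and 6 months; exponential for closed-form
  checkability), a per-group censoring coin (0.8 long / 0.15 intermediate /
  0 short, mirroring the censoring pattern of the real table), and truncation
  at a 100-month follow-up horizon. Overall survival adds an exponential
  post-progression interval calibrated to the gap between the group OS and
  PFS medians.

What the generator does **not** emulate: sequencing/quantification noise,
deconvolution error in the cell percentages, batch effects, non-exponential
(e.g. cure-fraction) survival, or any dependence between expression and
survival beyond group membership. Tests that pass on this generator therefore
validate the *estimators and the pipeline logic*, not the biological claims;
the bundled reference tables provide the exact printed values the worked
examples reproduce.

## Numerical and design choices

* Thresholds are midpoints, so ties at the cutoff are impossible on training
  data; on new data, `high_is_positive` calls values ≥ threshold positive and
  `low_is_positive` values < threshold, making the orientations exact
  complements.
* All percentage tie-breaking comparisons use a 1e-12 tolerance to keep
  floating-point noise from flipping deterministic choices.
* Analyte names are matched case-sensitively and exactly; no aliasing
  (PD-L1 ≠ PDL1).
* Analyses run on the primary recorded months by default; the parenthetical
  maintenance-adjusted months are available via `use_alt_months`.
* Registry survival recorded in days is converted by
  `days_to_months()` (× 12/365.25) only when the caller asks.

## Problem sizes used in the test suite

The packaged tests exercise the stochastic components at deliberately
moderate sizes chosen to keep the full suite in the minutes range while
retaining power: 200 random instances for threshold-oracle equivalence,
10⁵ permutation draws for the trend oracle and 10⁴ for the log-rank oracle,
50 seeds for subset-search recovery (planted log-effect 2 at n = 19),
100 seeds for hazard-ratio recovery at n = 200/arm, n = 300 for copula
recovery, and 2000 simulated null cohorts for type-I calibration of the
rank-sum and t tests. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Limitations

* The multidimensional metrics are not nested-CV estimates (see above).
* Under a true null (labels independent of the analyte), leave-one-out
  accuracy with a tuned threshold is *anti*-biased: it centers near 50%,
  below the majority rate (about 58% at 11 vs 8), because the held-out
  sample always opposes the direction the fold's threshold was tuned
  toward. Null LOO accuracies at or below chance are therefore expected
  behavior, not a bug, and the test suite asserts exactly that.
* A training fold whose features are all constant carries no split
  information; the forest step then falls back to the class prior
  (score = prior difference), which under leave-one-out predicts the
  majority of the *remaining* samples — another small-sample pathology the
  tie-handling tests exercise deliberately.
* The subset search is exhaustive only up to 8 candidates by design; the
  intended use is the top-5 ranking.
* The per-analyte p-value column assumes the rank-sum test, which the
  original protocol names only for baseline covariates; with the deposited
  data unavailable to this package, that assumption is untestable.
* The Mantel–Haenszel HR is biased toward 1 relative to a Cox estimate when
  arms cross; it is reported because it is the stated method.
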