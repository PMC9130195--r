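---
title: "Growth-informed PLS modelling of microbial LC-MS time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-informed PLS modelling of microbial LC-MS time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthpls)
library(dplyr)
```

## The problem

Untargeted LC-MS metabolomics of a microbial culture grown on solid medium
produces, after peak detection and binning, a small samples-by-bins intensity
table: a handful of incubation days, a few replicates per day, and a few
dozen integrated retention-time windows ("bins"). Two questions drive the
analysis of a feeding experiment in which an exogenous compound is added to
the culture:

1. Which metabolites are *produced* or *consumed* monotonically as the
   colony grows (medium components, constitutive metabolism)?
2. Which metabolites appear *transiently* — produced and consumed within a
   short window — as a response to the exogenous compound, and which of them
   qualify as *induced* relative to an unfed control?

Both questions are answered with supervised latent-variable models: partial
least squares regression (PLSr) against a continuous growth response, and
PLS discriminant analysis (PLS-DA) against incubation-day classes.
`growthpls` implements the full chain — preprocessing, response-vector
construction, a NIPALS PLS engine, validation, biomarker calls and
formula-based mass annotation — plus a synthetic-data generator that
emulates the study design with planted ground truth.

## The response model: why log colony diameter

Using the incubation day as the PLS response assumes metabolic change is
linear in calendar time. It is not: growth on a plate of limited medium
follows lag / exponential / stationary phases, and metabolite production
tracks growth and nutrient depletion rather than time. The package therefore
builds four candidate response vectors with `build_y()` — incubation days or
measured colony diameters, each raw or natural-log transformed — and lets
`compare_y_models()` pick among them by cross-validated fit.

The log-diameter response y(day) = ln(diameter in cm) has two convenient
anchors: a 1 cm colony (the inoculum plug) maps to exactly 0, and the 9 cm
plate bounds the trajectory. Replicates of a day share a response value.
For table-style display the package provides `truncate_decimals()`, which
truncates toward zero (ln 8 = 2.0794 prints as 2.07, not 2.08) — full
precision is always used in computation.

The winner rule is: among candidates whose three permutation p-values
(Wilcoxon, sign, paired t) all fall below 0.05, take the highest
cross-validated R² (Q²); ties break toward fewer latent components, then
listed order.

## Preprocessing chain

`run_preprocess()` applies, in order: retention-time trimming (closed
interval, default 11.5–31 min), signal-to-noise and replicate-occurrence
filters, the pooled-QC relative-standard-deviation filter (default 25%,
n−1 standard deviation, computed on raw intensities), blank subtraction,
then — on study samples only — total-area normalization, the generalized
logarithm, and autoscaling.

Decisions worth stating explicitly:

* **Filter placement.** Bin-level filters run on raw intensities *before*
  row normalization, so a discarded bin can never distort the total area of
  the surviving ones. The transforms run on study (B/F) rows only, so model
  scaling is estimated from exactly the samples the models see.
* **g-log form and scale.** g(x) = ln(x + sqrt(x² + λ)) with λ = 0.1 applied
  to unit-sum rows. The transform is scale-dependent, so λ refers to the
  normalized metric. The variant with a /2 inside the logarithm differs by
  the constant ln 2 and is absorbed by autoscaling — no downstream effect.
* **Whittaker baseline.** `baseline_whittaker()` minimizes
  Σ wᵢ(yᵢ−zᵢ)² + λ Σ(Δ²zᵢ)² with asymmetric weights (p where the signal
  exceeds the baseline, 1−p below), iterated at most 10 sweeps until no
  weight changes, second-order differences, corrected signal clipped at 0.
  Defaults λ = 100, p = 0.001. As λ → ∞ the baseline tends to the
  least-squares straight line; the test suite asserts this limit and
  equality with a dense direct solve to 1e−8.
* **Noise level.** When organic-solvent blanks exist, the SNR filter's noise
  level is their scaled median absolute deviation (×1.4826); otherwise it
  must be supplied (the protocol source does not define its estimator).
* **RSD degenerate case.** A zero-mean QC bin has undefined RSD and is
  removed with an explicit reason code.

## The PLS engine

`pls_nipals()` is a from-scratch NIPALS implementation. With a single
response the inner iteration closes in one step; with a one-hot class
matrix it alternates weight/score updates to a 1e−10 weight-change
tolerance (≤ 500 iterations), deflating both blocks. Numerical conventions:

* **Sign.** Each weight vector's largest-magnitude element is positive, so
  refits are bit-reproducible across platforms.
* **Coefficients.** B = W(PᵀW)⁻¹Qᵀ on the centered/scaled metric, with
  centers and scales stored on the model; cross-validation folds re-estimate
  both (no leakage — the protocol source is silent, so the conservative
  choice is made).
* **VIP.** VIPⱼ = sqrt(p·Σₐ SSYₐ w²ⱼₐ / Σₐ SSYₐ); squared VIPs sum to p on
  every model. Per-class VIPs restrict SSYₐ to one response column.
* **Class assignment.** Maximum predicted response column; exact ties go to
  the first class in encoding order and are flagged.
* **PCA/HCA.** PCA by SVD on the centered matrix with variances d²/(n−1)
  (summing to p for autoscaled input); clustering by Ward linkage
  (`ward.D2`) on Euclidean distances.

The engine is validated two ways in the test suite: at full rank its fitted
values equal ordinary least squares (1e−8), and at any fixed component
count they equal an independent SIMPLS implementation (1e−6) — an
algorithmically distinct formulation kept in the test helpers only.

## Validation

`loo_cv()` performs leave-one-out cross-validation, reporting RMSEC and
RMSECV per component count. `select_components()` takes the smallest count
whose RMSECV is within 1% of the minimum — complexity is never bought for
noise. Q² = 1 − PRESS/SStot may be negative and is never clipped.

`permutation_test()` refits the model on row-shuffled responses. The
empirical p is the rank of the true Q² in the null,
(1 + #{Q²perm ≥ Q²true})/(1 + n), never zero. Because the reference
software's permutation table is unpublished, the three paired tests are
defined here explicitly: per permutation, the true model's per-sample
absolute residuals are compared against the permuted model's (Wilcoxon
signed-rank, sign test, paired t, one-sided), separately for self-prediction
and cross-validated residuals; per-test p-values aggregate across
permutations by median, and each test reports the larger (more
conservative) of its SP and CV values. Default 1000 permutations, with any
count configurable (400 mirrors the printed table's caption). The test
suite verifies frequentist calibration: with Y independent of X, the
rejection rate at α = 0.05 over 200 replicate datasets stays inside the
exact binomial 99% interval.

## Biomarker calls

`classify_trend()` merges the two models into one call per bin: PLSr-VIP
above 1 with a negative/positive coefficient reads *consumed*/*produced*;
otherwise a bin whose PLS-DA association points at the day-4 class or the
merged day-8/12 class with a per-class VIP above 1 reads
*transient_early*/*transient_late*; anything else is *unchanged*. The
associated class is the argmax of the bin's PLS-DA coefficient row — the
loading-quadrant reading of a discriminant model. Per-class VIP magnitudes
alone do not localize a class, because shared latent components inflate
every class column; the coefficient sign pattern does, while the VIP still
gates relevance. Bins relevant to both models resolve in favour of the
regression reading, with the conflict recorded.

`induced_criterion()` flags a bin as induced when all three hold:
VIP > 1 (PLSr or any PLS-DA class), Welch t-test p < 0.005 between the
groups, and treatment/control mean-area fold ≥ 3 (control mean floored at
1e−12 of total area). Two implementation choices matter:

* **Areas, not transformed values.** Fold changes use the normalized
  (unit-total-area) stage, before the g-log, because the criterion speaks
  about peak areas.
* **The t-test window.** The test compares log-areas restricted to the
  bin's *expression window* — the days whose treatment-group day-mean
  reaches at least 5% of the bin's maximum day-mean. Pooling all days would
  dilute any day-limited signal below every reasonable significance level:
  with 15 samples per group of which only three carry a day-4 pulse, the
  pooled t statistic is bounded near 1.9 *regardless of the pulse
  amplitude*, so a pooled test could never flag a transient metabolite at
  p < 0.005. The log scale equalizes the two groups' multiplicative noise
  so the Welch degrees of freedom stay useful even when the control sits at
  the detection floor.

No multiple-testing correction is applied, matching the original protocol;
this is a real divergence risk for wider matrices and is deliberately
exposed rather than hidden.

`spearman_bin_correlation()` produces the bin-by-bin rank-correlation map
(average ties); it is invariant under strictly monotone transforms, which
the suite asserts by comparing before/after g-log.

## Mass annotation

`parse_formula()`, `monoisotopic_mass()`, `adduct_mz()` and `ppm_error()`
reproduce printed annotation tables. Two conventions are documented because
printed tables silently choose them:

* **Adduct mass.** Default is the neutral-atom convention (add the H- or
  Na-atom mass); the physically exact cation convention (minus one electron
  mass) sits behind `electron_correction = TRUE`. The neutral convention
  matches the reference values to four decimals.
* **Printed comparison.** Truncation at the printed precision, consistent
  with the reference tables' behaviour (4.57 prints as 4.5).

`match_shift()` matches precursor/product mass differences against a small
explicit biotransformation library (hydrogenation +2.015650, hydration
+18.010565, oxidation +15.994915, methylation, and reverses), within a ppm
tolerance of the product mass.

## The synthetic-data generator

`simulate_dataset()` emulates the study design: 2 groups × 5 incubation
days (1, 4, 8, 12, 16) × 3 replicates, 25 bins over RT 11.5–31 min, pooled
QC rows, and colony diameters (1, 3.19, 7.54, 8.41, 9) cm for the fed group
and (1, 4.9, 8, 8.5, 9) cm for the control. The growth signal is
g(day) = ln(diameter), tying the generator to the log-diameter response
model. Archetype mean trajectories:

| kind                 | count | trajectory                                            |
|----------------------|------:|-------------------------------------------------------|
| `media_decay`        | 5     | base·(1 − g/g_max), both groups                       |
| `growth_linked`      | 8     | base·g/g_max, both groups                             |
| `alkaloid`           | 2     | base·exp(−2.5 g) in B (< 1% of initial by day 12), floor in F |
| `early_pulse`        | 3     | base on day 4 only, B only                            |
| `late_pulse`         | 2     | base on days 8 and 12 only, B only                    |
| `stress_upregulated` | 1     | base·(0.3 + 0.7·g/g_max), ×4 on days 8–12 in B        |
| `inert`              | 4     | constant base, both groups                            |

This census yields 15 growth-monotone bins in the fed group, mirroring the
reference design's counts approximately. Replicate noise is multiplicative
lognormal with CV 0.10 — a free choice (the reference reports no
within-class variance), set comfortably below the 25% QC rejection bound —
applied after adding a constant floor of 0.1% of the median base intensity
so no intensity is ever exactly zero. QC rows are the pooled mean over all
study samples of both groups under the same noise model.

Ground truth marks growth-monotone kinds as PLSr-relevant, gives pulse bins
their class (day 4, or merged 8/12), and marks the feeding-only *produced*
kinds — the pulses — as induced. The fed alkaloid bins deliberately satisfy
the statistical induced criterion (they exist only in the fed group), so
recovery specificity on the default census is exactly 18/20: in the real
experiment such compounds are excluded by prior knowledge, not by the
criterion, and the generator preserves that property rather than hiding it.

What the generator does *not* emulate: m/z dimension, isotope/adduct
structure, retention-time drift between runs, heteroscedastic
detector saturation, and between-batch effects. Passing recovery tests
therefore demonstrate the *pipeline's* correctness on data with the assumed
statistical structure, not robustness to every artefact of real
acquisitions.

`render_chromatograms()`/`bin_chromatograms()` close the loop to
point-by-point traces: bins become Gaussian peaks (area = intensity) on an
optional smooth drift, and trapezoidal re-integration recovers the matrix
within 1%, which exercises the baseline corrector against a known truth.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed; the pipeline derives one
substream per stage so stages can be re-run independently. The shipped test
suite and the acceptance script use: 20 replicate synthetic datasets for
recovery studies, 99–999 permutations per test, and 200 replicates for the
null-calibration study — sizes at which the reported rates have standard
errors comfortably below the margins they are checked against, while the
whole suite stays inexpensive on one core.

## A worked run

```{r pipeline, eval = FALSE}
sim <- simulate_dataset(sim_config(seed = 1))
report <- run_pipeline(sim$feeding, sim$control, sim$growth,
                       seed = 11, n_perm = 199, truth = sim$truth)
report
tidy(report$y_comparison)
report$recovery
autoplot(report$plsr$B$cv)       # RMSEC/RMSECV vs components
plot_vip(report$plsr$B$vip)      # VIP bar chart with threshold
plot_spearman_heatmap(report$spearman)
```

## Known limitations

* PLS-DA class assignment is the simple maximum-response rule; no
  probabilistic (Bayesian-threshold) assignment is provided — ROC views are
  the threshold-based alternative.
* The permutation paired-test aggregation (median across permutations,
  max of SP/CV) is one defensible reading of an unpublished procedure;
  it is configurable but not claimed equivalent to any proprietary tool.
* Exact equivalence with the "Automatic Whittaker Filter" of commercial
  toolboxes is not claimed; the implemented scheme is the published
  asymmetric-least-squares iteration.
* OPLS/OPLS-DA, kernel and sparse PLS variants are out of scope, as are
  spectral-library searches and formula generation from mass.
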