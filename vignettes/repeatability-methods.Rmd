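---
title: "Assay repeatability and sample-size inflation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay repeatability and sample-size inflation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iccpower)
```

## The variance-components model

A high-throughput (multiplex) assay measures p analytes — microRNAs, mRNAs,
proteins, metabolites — on each biological sample, and a pilot experiment
runs some samples in technical replicate (split aliquots measured twice).
`iccpower` models the measured log-concentration of analyte k, sample i,
replicate j as

y_ij^(k) = mu + a^(k) + b_i^(k) + e_ij^(k),

with independent zero-mean Gaussian components: a^(k) is the analyte's
offset with *dynamic-range variance* v_d = V(a^(k)) — the spread of true
mean concentration across analytes; b_i^(k) is sample i's biological
deviation with *biological signal variance* v_b^(k); and e_ij^(k) is
measurement error with *experimental noise variance* v_e^(k). All variances
are in squared log-concentration units.

Three quantities drive everything downstream:

* **Repeatability (ICC)** R^(k) = v_b^(k) / (v_b^(k) + v_e^(k)): the
  proportion of observed per-subject variance at analyte k that is
  biological. R = 1 is a perfect instrument; R near 0 is noise-dominated.
* **The inter-replicate correlation** r: the Pearson correlation, across
  analytes, between two replicate measurement vectors of one sample — the
  number usually quoted next to replicate scatterplots.
* **The sample size inflation factor (SIF)** n / n0: how much larger a
  study must be than the perfect-instrument baseline n0.

## Why r is not a precision measure

As p grows, r converges in probability to
(v_d + v̄_b) / (v_d + v̄_b + v̄_e), where v̄_b and v̄_e are
analyte-averages. The dynamic range v_d appears in both numerator and
denominator: an assay whose noise is large relative to its signal still
shows r near 1 whenever its dynamic range is wide. `asymptotic_correlation()`
evaluates the limit, `replicate_correlation()` the finite-p statistic, and
`convergence_curve()` the resampling study showing how quickly r stabilizes
(on realistic components it is within 1% of its full-assay value by subsets
of about 100 analytes). The package deliberately offers no "is my r good
enough" helper: these diagnostics exist to demonstrate the confound, and
`simulate_confound_demo()` reproduces the pedagogical three-analyte picture.

## Estimation

`decompose_all()` fits each analyte by closed-form one-way random-effects
ANOVA (method of moments). With I samples, n_i replicates each, N = sum n_i:

* v̂_e = MSW = Σ_ij (y_ij − ȳ_i·)² / (N − I),
* v̂_b = (MSB − MSW) / n0′, MSB = Σ_i n_i (ȳ_i· − ȳ··)² / (I − 1),
  n0′ = (N − Σ n_i²/N) / (I − 1).

Closed forms were preferred over ML/REML because the parametric bootstrap
re-estimates everything hundreds of times per run. Negative v̂_b (possible
when sample means are more homogeneous than the noise predicts) is truncated
to zero — upward bias, lower mean-squared error; v̂_e is a mean square and
non-negative by construction. When v̂_b = v̂_e = 0 the analyte carries no
information and R is defined as 0, so it counts as unpowered at any SIF —
the conservative choice for design.

The dynamic-range variance has no canonical estimator in this setting; we
use the sample variance (denominator p − 1) of the per-analyte grand means
minus the average sampling variance of those means
(Σ n_i² v̂_b / N² + v̂_e / N per analyte), truncated at zero. The correction
removes the first-order inflation that estimation noise in the means would
otherwise add to v_d. Analyte-averages v̄_b, v̄_e are means of the
*post-truncation* estimates. Analytes with an inestimable design (fewer than
2 samples with data, or no replicated sample) are excluded with a logged
reason rather than failing the run. Missing cells are simply dropped: a
sample contributes to an analyte's fit only through its non-missing
replicates, and replicate indices are re-assigned 1..n_i (replicates are
exchangeable within a sample under the model, so identity carries no
meaning).

`ba_repeatability_coefficient()` provides the complementary
measurement-scale summary 1.96·sqrt(2 v̂_e), the 95% one-sided upper bound
on the absolute difference between two replicate readings.

## Sample-size planning

The reference design is the balanced two-group comparison with a two-sided
equal-variance t-test. For a targeted standardized effect
Δ = |mu_T − mu_C| / sqrt(v_b), `base_sample_size(delta, alpha, power)`
returns the smallest even total n0 = 2m whose noncentral-t power
(noncentrality Δ·sqrt(m/2), df = 2m − 2) reaches the target; at Δ = 1,
α = 0.05, power 0.8 this gives the textbook n0 = 34 (17 per group).

Measurement error inflates per-subject variance from v_b to v_b + v_e, so
the observable effect attenuates to Δ·sqrt(R). The inflation rule is: the
experiment is well powered at analyte k when SIF > 1/R^(k) — 1/R is exactly
the variance inflation factor of the noisy measurement. The planning
protocol is then: estimate R across the assay from a pilot; inspect
`power_table()` / `plot_powered_vs_sif()` to pick a SIF at which the desired
percentage of analytes clears its threshold (strict inequality; R = 0 is
never powered); compute n0 from Δ, α and power (Bonferroni-adjust α via
`bonferroni_alpha()` when testing every analyte); and set
n = SIF × n0, rounded **up to the next even integer** to preserve balanced
groups (`adjusted_sample_size()`; 1.1 × 34 = 37.4 becomes 38).

One property worth knowing: the 1/R threshold is a *sufficient* bound, not
a tight one. Because n0 is itself rounded up to an attainable even size
(power 0.807 rather than 0.800 at n0 = 34), sample sizes slightly below
SIF × n0 can still achieve the nominal power — e.g. exact power 0.819 at
n = 134 when R = 0.25 and n = 136 is the inflated size. The rule guarantees
power at or above target; it does not certify that anything smaller fails.
`achieved_power()` (analytic) and `mc_power_two_sample()` (simulation, kept
deliberately independent of the analytic route) let users check any
candidate n directly.

## Parametric bootstrap

Confidence intervals come from simulating n_boot full datasets at the fitted
parameter values under the original replication design (same samples, same
per-cell n_i), re-running the entire estimation on each, and taking
percentile intervals (`ci_percentile()`, the type-7 linear-interpolation
quantile). Analyte offsets a^(k) are *redrawn* from N(0, v̂_d) in every
replicate — analytes are exchangeable under the model — rather than
conditioned on the fitted means; the choice is recorded in the result
metadata. Per-analyte simulation uses the truncated (≥ 0) fitted variances.
Defaults: n_boot = 1000 for variance-component intervals, 200 for
%-powered curves (each draw re-estimates everything); percentile rather than
BCa intervals as the simplest defensible default, stated so users can
compare. A matrix-form fast path is used when every analyte shares the same
replication pattern; an equivalent long-format path handles arbitrary
missingness (the two are cross-checked in the test suite).

## The synthetic-data generator

`simulate_dataset()` draws from exactly the hierarchical Gaussian model
above: all three levels Gaussian, per-analyte v_b^(k) and v_e^(k) either
constant (for parameter-recovery oracles) or log-normal across analytes (to
emulate the wide repeatability spread real assays show), an optional
monotone `noise_link` making noise depend on concentration (a decreasing
link reproduces the familiar pattern that low-abundance analytes are harder
to measure), and a replication design in which the first n_replicated
samples get 2 replicates and the rest 1 — matching the usual pilot in which
only a subset of samples is duplicated. Default components in examples and
tests mirror published assay profiles (e.g. v_d = 3.57, v̄_b = 0.05,
v̄_e = 0.07 with 69 duplicated samples and p = 1624 for a microRNA-like
panel; v_d = 8.17, v̄_b = 0.04, v̄_e = 0.01 for a metabolite-like one).

What the generator does **not** emulate: missingness mechanisms,
limit-of-detection censoring, batch effects, heavy-tailed noise, or
correlation between analytes. Passing tests on synthetic data therefore
validate the estimators under the model's assumptions; they do not certify
robustness to those violations on real data.

## Numerical and testing choices

* Degenerate inputs: all-equal replicates give v̂_e = 0 exactly; identical
  sample means give v̂_b < 0 pre-truncation; both flow through.
* The running-quantile smoother (`running_quantiles()`) uses a Gaussian
  kernel with default bandwidth (concentration range)/10, weights
  renormalized per grid point, and weighted quantiles interpolated on
  midpoint cumulative weights; curves for increasing probabilities are
  ordered by construction. Histograms default to 30 bins for R and
  Freedman–Diaconis for concentration. Every figure writes TSV sidecars of
  its plotted layers so graphical claims are testable without image parsing.
* Simulation sizes in the test suite were chosen to make Monte-Carlo error
  small relative to the asserted tolerances while keeping a default run
  fast: 10^5 simulated experiments for power checks (MC SE ≈ 0.13% at 80%
  power), pilots of p = 200 analytes × 100 samples (50 duplicated) for
  parameter recovery, and 200 × 200 nested simulations for bootstrap
  coverage.
* Seeds: all stochastic functions take an explicit seed and are
  bit-reproducible given it; child seeds are derived by seeded sampling and
  stay below 2^31.

## Limitations

Only the balanced two-group design is supported (no paired, ANCOVA or
multi-arm layouts), only Bonferroni for multiplicity, and no
shrinkage/empirical-Bayes pooling of variance estimates across analytes.
The package starts from measured log concentrations: assay-specific raw-file
parsing, normalization and batch correction are out of scope.
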