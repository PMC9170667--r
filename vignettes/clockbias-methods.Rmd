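---
title: "Quantifying cohort bias in DNA-methylation age prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cohort bias in DNA-methylation age prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An epigenetic age predictor maps percent-methylation values at a handful of
age-associated CpG sites to a chronological-age estimate. Predictors for
minors are necessarily trained on healthy children, but in practice they may
be applied to children with clinical conditions — growth disorders being the
motivating case — whose methylation at *some* of those CpGs is altered by
the disease itself. The danger is a systematic over- or underestimation that
is nearly invisible in mean absolute error (MAE) but shows up clearly in the
signed **age gap** (predicted minus chronological age).

Quantifying that bias from a small clinical cohort faces two confounds:
training and testing must be strictly separated, and the clinical cohort's
age/sex composition differs from the healthy controls. The pipeline in this
package addresses both with matched paired subsampling: for each of many
runs, equal-sized test subsamples are drawn from the reference and the
target cohort, accepted only when statistically indistinguishable in age and
sex; the model is trained on the remaining reference samples and evaluated
on both (equally unseen) arms. Distributions of MAE and mean age gap across
runs then separate genuine cohort bias from composition effects.

## Pipeline and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| selection threshold | 0.75 | clock CpGs need Spearman R > 0.75 (signed, strict) vs age |
| ANCOVA alpha | 0.05 | per-CpG significance for a cohort effect, age-adjusted |
| test fraction | 0.10 | test arm size `m = ceil(0.10 * min(n_ref, n_target))` |
| matching threshold | 0.3 | both matching p-values must exceed 0.3 (strict) |
| runs | 25000 | full-scale protocol; desk-scale analyses use 50–200 |
| trees | 1000 | full-scale forest size; desk-scale 100 |
| min leaf size | 1 | trees grown to purity; bagging supplies the smoothing |

**Clock selection is signed.** Selection uses R > 0.75, not |R| > 0.75: a
strongly *negatively* age-correlated CpG would not be selected by default.
With buccal-swab panels the most negative correlations in this age range are
far from the threshold (around −0.4), so the two rules rarely disagree; an
`absolute = TRUE` switch exists for panels where they would.

**ANCOVA covariates.** The robustness screen fits
`beta ~ age + group` and F-tests the group coefficient (1 numerator df,
nested-model form). Sex is *not* in the default covariate set — sex
differences are screened separately and are null in the default generator —
but `include_sex = TRUE` adds it. No multiple-testing correction is applied
across the 22 CpGs; flags are per-CpG at α = 0.05, which callers should
treat as a screening, not confirmatory, threshold.

**Matching tests.** Age matching uses the two-sided Welch t-test, sex
matching Fisher's exact test; both remain well-defined at the smallest
subgroup sizes (m = 2), though with m = 2 their power is negligible and the
p > 0.3 filter is correspondingly weak — a documented caveat, honoured as
specified. Mann–Whitney and chi-square variants are available. "Unique"
subsamples are interpreted strictly: the *ordered pair* (reference index
set, target index set) may never repeat, tracked by fingerprint during
rejection sampling. Rejection sampling (rather than optimisation-based
matching) preserves exchangeability of accepted splits under the null.

## The regression-forest learner

The age model is a bagged ensemble of regression trees with:

- **Curvature-test split selection.** At each node, every predictor is
  tested for independence against the response: the predictor is binned
  into at most four quartile cells (type-7 quantiles at 25/50/75 %, values
  equal to an edge fall into the lower cell; a categorical predictor
  contributes its levels), the response likewise into quartile cells, and a
  Pearson chi-square test with `df = (r−1)(c−1)` is applied after dropping
  empty rows/columns. The predictor with the smallest p-value wins; a
  constant predictor gets p = 1 and is never preferred. This reduces the
  selection bias toward many-valued predictors that plain SSE search has.
  The binning internals of the original toolbox implementation are not
  published; the quartile-binning reconstruction here is documented as
  such, and `predictor_selection = "mse_exhaustive"` provides classic
  greedy CART selection as a reference alternative.
- **Cut search.** On the chosen predictor the cut maximises the reduction
  in the sum of squared errors over midpoints of sorted distinct values
  (categorical: exhaustive binary level partitions, ≤ 20 levels). If no
  valid cut respects the minimum leaf size, the next-best predictor by
  p-value is tried.
- **Small-node fallback.** The chi-square test needs ≥ 4 samples and ≥ 2
  distinct responses; smaller impure nodes (reachable at min leaf 1) fall
  back to exhaustive SSE selection so they can still split — required for
  the interpolation property of noiseless single trees.
- **Surrogate splits.** At every internal node, for each other predictor,
  the binary rule (threshold with orientation, or level partition) that
  best agrees with the primary split is retained if it beats the
  larger-child majority baseline; surrogates are ranked by agreement.
  Observations missing the primary predictor are routed by the first
  applicable surrogate, else to the larger child — at training and at
  prediction time.
- **Determinism.** All ties (feature ranking, cut candidates, surrogate
  ranking) break toward the lowest index / leftmost candidate. Bootstrap
  indices are the only randomness and are drawn in R under the supplied
  seed, so a fitted forest is a pure function of (data, parameters, seed).
  No per-node feature subsampling is used (all predictors compete at every
  node), and sex is feature 1, flagged categorical.

Forest predictions are tree means, hence always inside the training-age
hull — predictions can never overshoot the oldest training child, which
mildly compresses positive bias at the top of the age range.

## The synthetic-cohort generator

The generator exists so that every downstream stage can be validated
against known ground truth; it emulates the *statistical* structure the
pipeline assumes, not methylation biology:

- **Linear trajectories.** Percent methylation is
  `clip(intercept + slope·age + shift + ε, 0, 100)` with Gaussian ε.
  Childhood methylation kinetics are not truly linear, but over 0.42–18 y
  only rank correlation and predictive recoverability matter downstream,
  and linearity is the simplest structure that reproduces the observed
  correlation strengths.
- **Default panel.** 22 CpGs named after the genes of a standard buccal
  pyrosequencing panel: 11 clock CpGs (nine ELOVL2-like, one PDE4C-like,
  one RPA2-like) with population Spearman R above 0.8, and 11 weak CpGs
  (|R| ≤ 0.5) including negative-trend DDO/EDARADD sites reaching about
  −0.45. Six clock CpGs are disease-sensitive; the five robust sites are
  the ELOVL2 CpG1/2/5/8/9 analogues.
- **Noise scale 1.0 %.** Chosen so that simulated replicate re-measurements
  differ by ≤ 3 percentage points with probability
  `P(|N(0, 2·1²)| ≤ 3) ≈ 0.966`, matching the pyrosequencing QC convention
  that replicate runs agree within 3 %. `replicate_noise_check()` verifies
  this closed form by simulation.
- **Disease shift = slope × 2 years.** Sensitive CpGs in the disease
  cohort are displaced by the methylation a healthy child accrues in two
  years, i.e. the profile reads two years "too old" at those sites. No
  published effect sizes exist for the group differences (only
  significance), so this magnitude is a calibration choice, fixed once.
- **Sex neutral by default.** Screening found no sex differences in the
  motivating data, so sex affects nothing in the default generator (it
  remains a model feature, which is the point: a useless categorical
  predictor must not distort the forest).
- Ages uniform on 0.42–18 y, sex ratio 0.5; cohort specs accept fixed age
  sets and deliberately mismatched ranges to exercise the matching
  machinery, which raises an infeasibility error when no acceptable split
  exists (probed by a 100-attempt pilot).

What the generator does **not** emulate: cell-composition heterogeneity of
buccal swabs, nonlinear/pubertal kinetics, array-scale panels, imprinting
signatures, batch effects, or realistic biological scatter beyond the
technical-noise scale. Passing tests therefore demonstrate that the
*pipeline* recovers what it is supposed to recover from data obeying its
assumptions — not that any particular clinical cohort obeys them.

## What the pipeline recovers, and a structural note on dilution

With the default generator at n = 95/104, the screening stage recovers the
designed 11-CpG clock panel and the 6-sensitive/5-robust partition with the
power the test suite asserts (clock selection in ≥ 18/20 seeds; ANCOVA
power ≥ 0.9 at sensitive CpGs, false-flag rate ≈ α at robust ones). Under
the null (no shift) the matched gap and MAE differences are centred at zero
within ±0.3 y at 200 runs.

One quantitative point deserves emphasis. When 6 of 11 clock CpGs carry a
+2-year-equivalent shift, a predictor that weights clock CpGs by their
(here, nearly equal) informativeness can transfer at most about
6/11 × 2 ≈ 1.09 y of that shift into the mean age gap — and the forest's
realised transfer is further attenuated by the training-age hull and
leaf-mean averaging. The acceptance script computes this recovered bias
from scratch (`clock_bias_recovered`, ≈ 0.7–1.0 y across seeds at 200 runs
× 100 trees): positive, monotone in the injected shift, and much larger
than the robust model's gap (≈ 0), but necessarily *smaller* than the
injected 2 y. In real cohorts the same dilution applies: an observed mean
age gap understates the per-site displacement whenever the panel mixes
sensitive and robust sites — which is precisely why panels built from
robust CpGs are preferable for clinical target groups.

## Numerical choices and degenerate inputs

- Exact-fit residual sums below `1e-22 · Σβ² · n` are treated as zero in
  the ANCOVA F statistic, so noiseless null designs return F = 0, p = 1
  rather than numerical noise.
- Spearman correlation on a constant vector raises an explicit
  undefined-correlation error (screening converts it to
  `selected = FALSE` with a warning); ties get midranks.
- Zero-variance age vectors with equal means give matching p = 1;
  zero-margin sex tables give p = 1.
- Cohort CSV interchange writes 4-decimal fixed point; round trips are
  exact at that precision. Missing betas use the `NA` token; ages must lie
  in (0, 25) and betas in [0, 100], validated on every construction.
- Desk-scale defaults in the test suite and acceptance script — 200 runs,
  100 trees, n = 95/104, m = 10 — are the package's validation problem
  sizes; the full-scale 25,000 × 1000 protocol is configuration-reachable.

## Known limitations

- The curvature-test reconstruction is faithful to its published
  description but equivalence with the original toolbox's unpublished
  binning is not claimed.
- Per-run aggregation (MAE/gap per run, then means/medians across runs) is
  adopted; pooled-subject aggregation would weight runs by test-arm size
  identically here but differs in general.
- The package evaluates bias; it does not ship, and is not intended to
  ship, a casework-ready forensic age-estimation model.
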