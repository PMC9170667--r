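# clockbias

Epigenetic age predictors for children and adolescents are trained on
DNA-methylation (DNAm) levels at age-associated CpG sites in healthy
reference cohorts. When such a predictor is applied to a clinical target
group — for example children with growth disorders, whose methylation at
some of those CpGs is altered by the disease process — the predictions can
carry a *systematic* bias that ordinary accuracy metrics largely hide.
`clockbias` implements, as a tested and reusable pipeline, the procedure
for detecting and quantifying that bias:

1. **Marker screening.** Per CpG, the Spearman rank correlation *R* between
   percent methylation and chronological age in the healthy cohort; CpGs
   with *R* > 0.75 form the **clock panel**. An ANCOVA (methylation ~ age +
   group) then tests each CpG for a cohort difference at α = 0.05; clock
   CpGs *without* a significant difference form the **robust panel**, the
   significant remainder are the **sensitive** CpGs liable to induce bias.
2. **Matched paired subsampling.** Repeatedly, an equal-sized test subset
   is drawn from each cohort — `m = ceil(0.10 · min(n_ref, n_target))` per
   arm — and accepted only when the arms are statistically indistinguishable
   in age (Welch t-test) and sex (Fisher's exact test), both p > 0.3, and
   the pair of index sets has not been used before. The reference test
   subjects are set aside, so ≥ 90 % of the reference cohort trains the
   model and both test arms are equally unseen.
3. **Age model.** A bagged ensemble of regression trees (default 1000) on
   chronological age, with the panel CpGs plus sex (categorical) as
   features: split predictors chosen by the *curvature test* (minimum
   p-value of a chi-square independence test between each binned predictor
   and the binned response), minimum leaf size 1, and surrogate splits at
   every internal node for missing values.
4. **Bias evaluation.** Per run and per arm, the mean absolute error
   (MAE, years) and the mean **age gap** (predicted − chronological age;
   positive = overestimation); means and medians are aggregated across
   runs for the clock and robust models.

Because per-sample clinical methylation data are rarely shareable, the
package ships a synthetic-cohort generator with known ground truth
(per-CpG linear age trajectories over 0.42–18 y, pyrosequencing-scale
noise, and additive disease shifts at a designated sensitive subset), so
every stage of the pipeline can be validated end to end.

## Worked example

```r
library(clockbias)

panel <- default_panel()                       # 22 CpGs, known ground truth
ref <- generate_cohort(panel, cohort_spec(95), seed = 101)
gd  <- generate_cohort(panel, cohort_spec(104, group = "growth_disorder"),
                       apply_disease_shift = TRUE, seed = 102)

sel    <- select_clock_cpgs(ref, threshold = 0.75)
anc    <- ancova_screen(ref, gd, alpha = 0.05)
panels <- assign_panels(sel, anc)
panels
#> clock panel (11): ELOVL2_CpG1, ELOVL2_CpG2, ELOVL2_CpG3, ELOVL2_CpG4, ELOVL2_CpG5, ELOVL2_CpG6, ELOVL2_CpG7, ELOVL2_CpG8, ELOVL2_CpG9, PDE4C_CpG1, RPA2_CpG3
#> robust (5): ELOVL2_CpG1, ELOVL2_CpG2, ELOVL2_CpG5, ELOVL2_CpG8, ELOVL2_CpG9
#> sensitive (6): ELOVL2_CpG3, ELOVL2_CpG4, ELOVL2_CpG6, ELOVL2_CpG7, PDE4C_CpG1, RPA2_CpG3

cmp <- run_comparison(ref, gd, panels, n_runs = 50, n_trees = 100, seed = 103)
cmp
#> bias_comparison: 50 runs x 2 model(s), m = 10, 100 trees
#>   [clock] target group 'growth_disorder' (50 runs)
#>     test samples:      MAE mean 1.11 median 1.08 | age gap mean +0.99 median +0.95
#>     reference samples: MAE mean 0.74 median 0.72 | age gap mean +0.02 median +0.01
#>   [robust] target group 'growth_disorder' (50 runs)
#>     test samples:      MAE mean 0.80 median 0.81 | age gap mean -0.06 median -0.10
#>     reference samples: MAE mean 0.89 median 0.87 | age gap mean -0.02 median -0.08
```

The screening recovers exactly the 11 CpGs built into the generator as
age-associated, and partitions them into the 5 robust ELOVL2 sites and the
6 disease-sensitive sites. In the matched comparison the clock model
overestimates the ages of the disease cohort by about +1 year on average
(age gap +0.99 vs +0.02 in the matched healthy arm), while the robust
model — trained on the same splits but using only the robust CpGs — shows
essentially no systematic gap (−0.06). That contrast, not raw MAE, is the
bias signal: the clock-model MAEs differ far less than the gaps do.

`report_bias(cmp, "results/")` writes the per-run long table and a
block-structured summary table (one block per target group, test and
reference rows, mean/median MAE and age gap per model).

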