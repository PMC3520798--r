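# sexdiffr

Multi-cohort meta-analysis of molecular sex differences in serum.

Many medical conditions — autoimmune, cardiovascular, psychiatric —
differ between the sexes in prevalence, course, and treatment response.
A prerequisite for studying such disease-related dimorphism is a solid
map of which serum molecules differ between typical males and females,
estimated in a way that is robust to the heavy skew of immunoassay data
and to heterogeneity between independently recruited cohorts. sexdiffr
implements that analysis as a tested, reusable R pipeline for
epidemiologists and biostatisticians working with multiplexed serum
analyte panels.

## The statistical core

For analyte *a* in cohort *h*, the male–female difference is measured
with the nonparametric **Cliff's delta**

δ̂ = (1 / mn) Σᵢ Σⱼ sign(xᵢ − yⱼ),  δ ∈ [−1, 1],

(positive = higher in males), computed by an exact O((m+n) log(m+n))
rank algorithm, with Cliff's consistent variance estimator. Per-cohort
deltas are pooled with **DerSimonian–Laird random-effects
meta-analysis**: w = 1/v, Q = Σ w(δ − δ_FE)², τ² = max(0, (Q − (k−1))/C),
δ* = Σ w*δ / Σ w* with w* = 1/(v + τ²), requiring at least three
cohorts per analyte, with a χ²ₖ₋₁ heterogeneity test and
**Benjamini–Hochberg** FDR control (significance at q < 0.05).

Around that core the pipeline provides:

* **Pre-processing** in a fixed order: greedy male–female matching on
  covariates (Gower distance); replacement of out-of-range assay values
  by half the analyte minimum / double the maximum; elimination of
  analytes with more than 70% missing cells; single-pass exclusion of
  values more than 4 SD from the pooled mean.
* **Functional grouping**: k-means (k = 6, 50 restarts) of standardized
  analyte profiles on the largest cohort, with seeded uniform
  replacement of outlying cells.
* **Composite variables**: the first principal component of each
  cluster's standardized analytes per cohort, sign-oriented by the
  average loading sign of the top-loading analytes, pooled across
  cohorts with the same random-effects model.
* **Sex-by-condition interactions**: two-way ANOVA of composite scores
  against a disease cohort, BH-adjusted across clusters.
* **Synthetic studies**: a generator reproducing the structure of a
  nine-cohort study (392 controls, 196 M / 196 F, cohort sizes
  40/50/14/20/26/22/162/44/14, one 44-sample case cohort, 174 analytes
  in 6 latent clusters) with full ground truth, so every stage is
  testable without clinical data.

## Worked example

```r
library(sexdiffr)

run <- run_pipeline(run_config(seed = 42))   # simulates, then analyses
run
#> <study_run>
#>   samples: 436/436 retained after matching
#>   analytes: 174 retained, 174 pooled, 76 significant

report_summary(run)
#> Significant analytes (q < 0.05): 76
#>   male_higher: 37
#>   female_higher: 39
#> Composite sex differences (male - female, pooled):
#>   cluster 1: +4.634 [4.413, 4.855]
#>   ...
#> Sex-by-condition interaction:
#>   cluster 5: p = 6.888e-09, q = 4.133e-08  <-- significant
```

Of the 174 simulated analytes, 76 show a reproducible sex difference at
q < 0.05 (37 male-higher, 39 female-higher — the generator plants
effects in both directions). The composite table gives each analyte
cluster's pooled male-minus-female difference with its 95% CI, and the
interaction section flags the cluster whose sex difference deviates in
the disease cohort — here cluster 5, which contains the analytes
carrying the planted sex-by-condition interaction.

Individual stages are ordinary functions over tibbles and compose with
the pipe:

```r
sim    <- simulate_study(default_design(seed = 1))
clean  <- preprocess_panel(sim$panel, run_config())
pooled <- clean$panel |> cohort_effects() |> run_meta(alpha = 0.05)
tidy(pooled)     # one row per analyte: delta*, CI, p, q, Q, tau2, ...
autoplot(pooled) # forest plot of pooled deltas
```

Panels are read and written as wide delimited text with configurable
out-of-range sentinels (`read_panel()`, `write_panel()`); results
serialize via `write_effect_table()`.

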