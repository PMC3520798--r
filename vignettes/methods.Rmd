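---
title: "Methods: multi-cohort meta-analysis of serum sex differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort meta-analysis of serum sex differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind sexdiffr, the
choices made where the procedure admitted more than one reasonable
reading, and what the synthetic-data generator does and does not
emulate. It is the package's methods reference; the README shows usage.

## The analysis model

The pipeline asks, for each serum analyte measured across several
independently recruited cohorts, whether its concentration differs
reproducibly between typical males and females, and whether the sex
difference of a functional *group* of analytes deviates in a disease
cohort.

**Effect size.** Within each cohort, the male–female difference is
summarised by Cliff's delta, δ = P(X > Y) − P(X < Y), estimated by the
mean of sign(xᵢ − yⱼ) over all male–female pairs. Cliff's delta is used
rather than a mean difference because immunoassay concentrations are
strongly right-skewed, often censored at the assay's linear range, and
measured on analyte-specific scales; a rank-based effect size is
invariant to monotone transformations and bounded on [−1, 1], which
makes it poolable across analytes and cohorts. Positive values mean
male-higher. The implementation computes the pairwise count exactly
from midranks in O((m+n) log(m+n)); the test suite pins exact equality
with the O(mn) dominance-matrix count on a thousand random tied
instances.

**Variance.** Cliff's consistent estimator is used,

v = [n²Σᵢ(dᵢ. − δ)² + m²Σⱼ(d.ⱼ − δ)² − Σᵢⱼ(dᵢⱼ − δ)²] / [mn(m−1)(n−1)],

obtained from rank counts without forming the dominance matrix. The
choice of estimator is a design decision — the analysis requires *some*
per-cohort variance for inverse-variance pooling, and Cliff's
consistent form is the standard in that literature; a Monte-Carlo
calibration test (500 replicates at m = n = 50, null and δ ≈ 0.5)
guards the choice to within 15%. Two degenerate cases need floors. If
the formula returns a non-positive value on non-degenerate data, the
floor (1 − δ²)/(mn − 1) is used. At complete separation (|δ| = 1) that
floor is itself zero, so it is evaluated at the continuity-shrunk value
(mn − 1)/mn instead; without this, an analyte with complete separation
in one small cohort would get infinite weight and break the pooling.
Such analytes are expected — hormone-dominated analytes can separate
the sexes almost completely — so they must contribute finite, large
weight rather than be dropped.

**Pooling.** Per-cohort deltas are combined with DerSimonian–Laird
random-effects meta-analysis on the raw delta scale. DL is the
canonical moment estimator in the applied meta-analysis literature and
needs no iteration; REML is deliberately out of scope. Pooling on the
raw δ scale (no Fisher-type transform) matches how pooled deltas and
CIs are conventionally reported on [−1, 1]; interval ends are truncated
to the parameter space. A minimum of three cohorts per analyte is
enforced — with fewer, τ² is essentially unidentified; excluded
analytes are retained in the output with a flag rather than silently
dropped. Heterogeneity is tested per analyte by referring Cochran's Q
to χ²ₖ₋₁; the per-analyte choice (rather than a single global test) is
the only reading that yields a well-defined procedure for 174 analytes.
All pooled p-values are Benjamini–Hochberg adjusted; significance is
read at q < 0.05.

## Pre-processing

The order is fixed: matching → out-of-range replacement → missingness
filter → outlier exclusion.

1. **Matching.** Within each cohort, males and females are paired 1:1
   by a Gower-style distance over age, BMI, waist circumference,
   smoking and cannabis use: numeric covariates contribute
   |difference| / within-cohort range, categorical ones a 0/1 mismatch;
   covariates missing for either member, or with zero range, are
   skipped with weight renormalisation, so cohorts with sparse metadata
   degrade gracefully. Pairs are accepted greedily in order of
   distance (ties broken by sample id) — transparent and deterministic;
   an optimal-assignment variant was considered and not implemented, as
   greedy matching on these small cohorts is within a pair swap or two
   of optimal and easier to audit. Unmatched samples are removed, so
   every retained cohort is exactly balanced.
2. **Out-of-range replacement.** Cells censored by the assay are set to
   half the analyte's minimum (below range) or double its maximum
   (above range), computed over usable cells across the whole panel,
   and become ordinary values. This is the standard crude imputation
   for limit-of-detection data in immunoassay panels.
3. **Missingness filter.** Analytes whose fraction of *unmeasured*
   cells strictly exceeds 0.70 are eliminated. Replaced out-of-range
   cells do **not** count as missing: a censored cell was measured (the
   assay saturated), an empty cell was not. Because only truly
   unmeasured cells count, this filter commutes with outlier removal;
   the binding order constraint is that replacement precedes both, and
   the suite pins that a replaced cell can subsequently be removed as
   an outlier.
4. **Outlier exclusion.** Per analyte, values more than 4 SD from the
   mean are flagged and treated as missing downstream. The mean and SD
   are computed over all cohorts pooled ("overall mean" read literally)
   in a **single pass** — the rule is not iterated, so the flagged
   value itself inflates the SD used to judge it. A consequence worth
   knowing: with n present values the largest attainable z-score is
   (n−1)/√n, so the 4-SD rule cannot fire at all for analytes with
   fewer than 18 present values; the acceptance suite pins this
   behaviour on a 10-sample toy panel where a leave-one-out rule would
   have removed a planted spike. Strict inequalities (">") are used for
   both the 70% and the 4-SD rules, following the usual wording "more
   than".

## Clustering and composites

Analytes are grouped by k-means (Euclidean distance, k = 6 by default,
50 seeded restarts, best within-cluster sum of squares kept, ties by
restart order) on their standardized profiles over the *largest*
cohort only — the reference cohort has the most samples and therefore
the most stable correlation structure, and fitting on one cohort avoids
leaking between-cohort batch structure into the groups. Before
clustering, cells flagged by the same 4-SD rule (within the reference
cohort) are replaced by a uniform draw between the analyte's
non-outlying minimum and maximum, under a fixed seed; k-means minimises
squared distances and a single extreme cell would otherwise dominate an
analyte's profile. Cluster assignments depend only on the reference
cohort; the suite asserts that adding or removing other cohorts leaves
the model untouched.

Each cluster is summarised per cohort by the first principal component
of its standardized analytes (missing cells contribute 0 on the
standardized scale — mean imputation, the minimal choice that keeps the
decomposition defined). Because an eigenvector's sign is arbitrary,
scores are oriented by the *average sign of the top-loading analytes*:
analytes with |loading| in the top quartile (at least 3; both
parameters configurable) vote with the sign of their loading, and if
the votes sum negative, scores and loadings are flipped. Ties cascade:
vote sum zero falls back to the sign of the summed loadings, then to
+1. The oriented composite is invariant under (scores, loadings) →
(−scores, −loadings), which is the point of the rule, and equivariant
under negating the data. Scores are kept on the natural PC1 scale; no
per-cohort rescaling is applied. We examined rescaling variants
(dividing scores by their total or residual SD) and rejected them: any
normalisation estimated from data that contain the group structure
couples the composite's scale to the very effects being tested and
visibly distorts the operating characteristics of the interaction test
below.

Per cohort, the composite sex difference is the raw mean difference
d_h = mean(male) − mean(female) with Welch variance s²_m/n_m + s²_f/n_f,
pooled across cohorts with the same DL machinery as the analyte-level
meta-analysis (on the unbounded difference scale, so no CI truncation).
A Cliff's-delta-on-composites variant was considered and not made the
default: the cluster-level display is conventionally a difference of
composite values.

**Interaction testing.** For each cluster, a two-way fixed-effects
ANOVA (score ~ sex × condition) compares one designated control cohort
with the case cohort; the interaction F-test asks whether the
male–female composite difference differs between conditions, and
interaction p-values are BH-adjusted across the k clusters. The
comparison cohort defaults to the control cohort whose per-sex size is
closest to the case cohort's, the least-arbitrary single choice when
the design does not name one; it is configurable
(`comparison_cohort`). If a design cell is empty the test aborts naming
the cell; if the residual mean square is numerically zero the F
statistic diverges and the p-value is reported at the machine floor
with a `degenerate` flag. One property deserves emphasis: when a large
coherent sex effect is present in both cohorts, the column
standardization inside the composite slightly absorbs the estimated
gap, making the interaction test mildly *conservative*; its type-I
rate is nominal under a global null, which the suite verifies at 1,000
replicates.

## The synthetic-data generator

`default_design()` encodes the study conditions: nine control cohorts
with per-sex sizes 20/25/7/10/13/11/81/22/7 (392 controls, 196 male,
196 female), one 22/22 case cohort, 174 analytes in six latent
clusters. For sample *s* (cohort *h*, sex *g*, condition *c*) and
analyte *a* in cluster κ,

log X = μ_a + γ_{a,h} + λ_κ u_{s,κ} + β_a (1 + b_{a,h}) 1(g = F)
        + ι_a 1(F) 1(case) + ε,

with u ~ N(0,1) shared by a cluster's analytes within a sample,
b ~ N(0, τ_rel²) per analyte and cohort, ε ~ N(0, σ_a²). Concentrations
are exp(log X), censored below/above per-analyte limits, thinned by
missing-at-random cells, and salted with multiplicative outliers.

Choices and rationale, fixed once:

* **Log-normality** — immunoassay panels are positive and right-skewed,
  and the log-normal admits a closed-form ground truth: the marginal
  male-versus-female Cliff's delta is 2Φ(−β/(√2 σ_tot)) − 1 with
  σ_tot² = λ² + σ², which parameter-recovery tests exploit.
* **Dispersion** — residual log-SDs are drawn from U(0.45, 0.55),
  typical of serum analyte panels (a coefficient of variation around
  50–60%); λ = 0.28 gives a within-cluster log-scale correlation of
  about 0.24, a realistic strength for functional protein clusters.
* **Heterogeneity** — between-cohort variation multiplies the sex
  effect (β(1 + b), τ_rel = 0.3) rather than shifting the mean,
  because it is the *effect sizes* the random-effects model pools;
  additive site shifts exist separately as γ (SD 0.3) and cancel out
  of within-cohort comparisons.
* **Effects** — 45% of analytes carry a sex effect, with target deltas
  of alternating sign and magnitudes U(0.15, 0.85), mirroring a panel
  in which roughly equal numbers of analytes are female- and
  male-elevated across a wide effect range. One cluster carries a
  female-case interaction shift of −0.8 σ_tot.
* **Censoring, missingness, outliers** — detection limits are placed at
  roughly the 1.5th and 99.5th percentile of each analyte's marginal
  distribution; 2% of cells are missing at random; 0.5% are multiplied
  by 8.
* Covariates are simulated as pure nuisance (independent of sex), so
  matching is exercised without confounding.

What the generator does **not** emulate: assay chemistry and plate
effects, longitudinal sampling, covariate confounding by sex (body
composition differs between sexes in reality), non-log-normal tails,
and correlated missingness. Passing tests therefore demonstrate that
the *procedure* recovers the structure it assumes, under realistic
sizes and noise — not that the model captures every feature of real
serum data.

## Problem sizes in the test suite

The statistical acceptance checks run at their full stated replication
counts: 1,000 random instances for the delta and BH oracles, 500
replicates for closed-form recovery, variance calibration, and CI
coverage, 50 global-null studies for FDR control, 100 replicates for
analyte-level power and composite direction, and 1,000 + 200
replicates for interaction calibration and power. Coverage is
evaluated at δ_true = −0.2 — comfortably inside the parameter space,
where the delta-scale nonlinearity of the heterogeneity mapping is
mild; DL intervals are known to run a few points below nominal at
k = 9 regardless of effect size, which the 90–98% acceptance band
anticipates. Cluster-recovery checks use λ = 0.6 ("strong separation",
within-cluster correlation ≈ 0.6) because that is the regime the
recovery claim is about; the default design's weaker λ = 0.28 yields
partial recovery, which is reported descriptively by the acceptance
script, not asserted.

## Known limitations

* Confidence intervals for single-cohort deltas use the normal
  approximation, truncated to [−1, 1]; asymmetric (Fisher-type)
  intervals are not implemented.
* The DL estimator's slight undercoverage at k = 9 is inherited by
  design; a Hartung–Knapp or REML variant would be the natural
  extension.
* Greedy matching is not globally optimal; with very unbalanced
  covariate distributions an assignment solver would retain slightly
  better-matched pairs.
* The interaction ANOVA uses one control cohort, not all nine; pooling
  controls would change both power and interpretation.
* Functional annotation of clusters (pathway enrichment, networks) is
  out of scope — cluster labels here are structural, not biological.
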