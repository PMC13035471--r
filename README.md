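# screeneval

Tools for evaluating a standalone AI reader against human readers in
**double-read breast cancer screening**, and for managing its deployment.

In double-read programmes (the UK NHS Breast Screening Programme among them),
two readers independently assess each mammogram and disagreements go to an
arbitration panel. Replacing the second human reader with an AI system raises
a chain of questions this package operationalises:

* **Is the AI as accurate as a human reader?** Paired noninferiority and
  superiority testing of sensitivity and specificity at the case, breast and
  lesion level, against a ground truth defined by follow-up (a cancer within
  39 months of the index screen, or a within-episode definition for
  prospective monitoring).
* **Is it fair?** Subgroup performance and score-calibration audits across
  age, deprivation (IMD), ethnicity, breast density, device and screen type.
* **What does it do to the workflow?** Simulation of the double-read
  arbitration rules per arm, with workload in *equivalent reads* (one
  arbitration ≈ 5 single reads, from 132 s vs 25 s average read times).
* **How is it kept safe after deployment?** Operating-point selection on
  tuning data, recall-rate proxy monitoring (trigger when AI recall exceeds
  the first reader's by > 2 percentage points, or predicted arbitration
  reaches 2.5× the human-only rate) and threshold recalibration under
  distribution shift.

Because the real screening data such studies use are held under restricted
access, the package includes a first-class **synthetic cohort generator**
whose defaults emulate the published summary characteristics of a
five-service UK programme (~1.7% cancer outcome rate split into
screen-detected / interval / next-round components, reader-clustered recall
decisions, device-conditional AI scores, lesion bounding boxes and candidate
AI regions of interest). Every downstream stage is therefore testable
offline.

## Statistical core

For paired decisions on the same episodes, the difference in sensitivity (or
specificity) between AI and a comparator reader is tested against an absolute
noninferiority margin of 5 points with a one-sided Wald test at level 0.025,

&nbsp;&nbsp;&nbsp;&nbsp;z = (Δ̂ + δ) / √V̂,&nbsp;&nbsp; δ = 0.05,

where V̂ is a cluster-robust (Obuchowski-type) variance over reader clusters
*i* with sums *S·i*, sizes *m·i* and grand mean difference D:

&nbsp;&nbsp;&nbsp;&nbsp;V̂ = I/(I−1) · Σᵢ (Sᵢ − mᵢ D)² / N².

With singleton clusters this reduces exactly to the classical paired
variance var(d)/n. The z statistic is referred to a t distribution with
(clusters − 1) degrees of freedom, the standard small-sample correction for
cluster-robust inference. If noninferiority is shown, a one-tailed
superiority test follows (no extra multiplicity), using the clustered
extension of McNemar's test, T = (Σᵢ gᵢ)² / Σᵢ gᵢ² with per-cluster
discordant differences gᵢ — which reduces to (b−c)²/(b+c) for singleton
clusters. The primary endpoint family is Holm–Bonferroni corrected;
confidence intervals are Wald when the denominator has ≥ 50 units and
case-level percentile bootstrap (10,000 iterations) otherwise and for
PPV/NPV and breast/lesion-level quantities. Lesion localisation uses
IoU > 0.1 box matching with hits in either view, an any-focus rule for
multifocal breasts, and FROC curves over the ROI score range.

## Worked example

```r
library(screeneval)

cohort <- generate_cohort(cohort_config(n_women = 25000, seed = 2024))
kept   <- apply_exclusions(cohort$episodes)
labels <- label_cases(kept$included, window_months = 39)
e      <- kept$included[match(labels$episode_id, kept$included$episode_id), ]

compare_readers(e$ai_score > 0.5, e$reader1_recall, labels$case_label,
                e$reader1_id, metric = "sensitivity")
#> case-level sensitivity: AI 0.5297 vs reader 0.4561 (diff +0.0736, 95% CI 0.0307..0.1166)
#>   noninferiority p = 9.6e-06 (margin 0.05); superiority p = 0.00338; verdict: noninferior_and_superior
#>   n = 421 units in 20 clusters
```

The AI finds 53% of the 421 in-window cancers against the first reader's
46%; the lower CI bound of the difference clears the −5-point margin by a
wide margin, so the cascade proceeds to superiority, which it also passes.
The same call with `metric = "specificity"` yields a −0.8-point difference —
noninferior (p ≈ 8e-21) but not superior.

Workflow consequences of substituting the AI for the second reader on the
same cohort:

```r
wf     <- workflow_config()   # discordant-only arbitration, 5-read arbitration cost
human  <- run_arm(e, labels, "human_double",  wf)
withai <- run_arm(e, labels, "human_plus_ai", wf)
compare_arms(withai, human)
#>            quantity value_a value_b pct_change
#> 1  equivalent_reads   36644   58388  -37.2
#> 2   screening_reads   23309   46618  -50.0
#> 3 arbitration_reads    2667    2354  +13.3
```

Human screening reads halve (the AI consumes none), arbitration load rises,
and total workload in equivalent reads falls by ~37%. Detection outcomes
under simulated arbitration depend on the configured panel model and are
labelled as such.

`run_pipeline()` chains generation, exclusions, labelling under both the
39-month and within-episode windows, metrics, inference, fairness,
calibration, workflow simulation and monitoring into one reproducible
report bundle (CSV/JSON with config digest and seed).

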