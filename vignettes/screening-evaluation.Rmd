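---
title: "Methods: evaluating an AI reader in double-read screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating an AI reader in double-read screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screeneval)
```

## The evaluation problem

Double-read screening programmes assess each mammogram twice and arbitrate
disagreements. Evaluating an AI system as an independent second reader
requires more than a headline AUC: decisions are **paired** (AI and human
read the same episodes), **clustered** (one reader contributes thousands of
screens, so reads sharing a reader are correlated), and the ground truth is
**longitudinal** (a "normal" screen is only known to be normal once the
woman returns, cancer-free, at the next round). This package implements
that evaluation chain end to end, together with the deployment machinery —
operating-point selection, drift monitoring, recalibration — that a real
service needs after go-live.

## Ground truth

An episode is labelled positive when a documented cancer falls within the
follow-up window of the index screen; `label_cases()` defaults to 39 months,
which accommodates slippage around the intended 3-year interval. Cancers are
carried as three outcome classes: *screen-detected* (confirmed at the index
episode), *interval* (symptomatic presentation between screens) and
*next-round* (found at the subsequent routine screen). A negative label
requires a confirmatory re-attendance 24–39 months later; episodes with
neither a cancer record nor such follow-up are excluded with reason
`"no ground truth"` rather than assumed negative.

Two boundary decisions are deliberate and documented here:

* the window is **inclusive** at its edge (a diagnosis at exactly 39.0
  months counts as in-window);
* the within-episode definition used for prospective monitoring is
  implemented as a 3-month window, under which only screen-detected cancers
  are positive;
* a cancer found at an early re-attendance (< 24 months) is treated as an
  interval cancer — the class boundary is presentation route, not clock
  time, and the generator records the route directly.

Risk classes follow pathology: invasive and high-grade in-situ disease are
*higher risk*; low/intermediate-grade in-situ disease is *lower risk*.

## Clustered paired inference

The primary endpoint is a 5-point absolute noninferiority margin on the
case-level sensitivity and specificity differences against the first reader,
tested one-sided at 0.025 with a Wald statistic. The variance of the paired
difference is the cluster-sum sandwich

$$\hat V = \frac{I}{I-1}\,\frac{\sum_i (S_i - m_i \bar D)^2}{N^2},$$

over reader clusters $i$ with per-cluster sums $S_i$ of the paired
indicator differences $d \in \{-1, 0, 1\}$. Three properties motivate this
form: it reduces *exactly* to the unbiased paired variance
$\operatorname{var}(d)/n$ for singleton clusters (the package's central
oracle test, at tolerance 1e-12), it agrees with a cluster-resampling
bootstrap on heterogeneous fixtures, and it needs no model for the
within-cluster correlation. Clusters are capped (default 1,000 reads) with
deterministic round-robin splitting; the cap value is a parameter, not a
claim about any particular programme.

With a modest number of reader clusters the plug-in variance is noisy and a
normal reference is anticonservative; `noninferiority_test()` therefore
refers the statistic to a $t_{I-1}$ distribution, the standard small-sample
correction in cluster-robust practice. A simulation at the margin boundary
(2,000 cohorts of 5,000 paired reads in 20 reader clusters, marginal
difference exactly −5 points by construction) puts the empirical one-sided
size at ≈ 0.025–0.028 against the nominal 0.025, within three Monte-Carlo
standard errors; `boundary_type1_error()` reproduces this and
`scripts/acceptance.R` reports it.

Superiority, tested only after noninferiority succeeds (a gated cascade, so
no additional multiplicity is spent), uses the clustered McNemar statistic
$T = (\sum_i g_i)^2 / \sum_i g_i^2$ on per-cluster discordant differences;
for singleton clusters this is the familiar $(b-c)^2/(b+c)$. Balanced
discordance ($\sum g_i = 0$) carries no directional evidence and reports
$p = 1$; zero discordance is flagged as degenerate. The primary family is
Holm–Bonferroni corrected; secondary and subgroup analyses are exploratory
and deliberately unadjusted.

Confidence intervals follow a stated policy: Wald when the relevant
denominator has at least 50 units (sensitivity, specificity, CDR, recall
rate), percentile bootstrap otherwise and always for PPV/NPV, resampling at
the case level so breast- and lesion-level rows move with their episode.
The percentile interval (rather than BCa) was chosen for simplicity and
reproducibility; 10,000 iterations by default, seeded. Zero denominators
report `NA` ("undefined"), never 0.

## Lesion localisation

Boxes are axis-aligned, half-open rectangles in pixel coordinates
(origin top-left); IoU of degenerate zero-area boxes is defined as 0. A
lesion counts as localised when a same-side ROI in at least one view
exceeds IoU 0.1 (strict). Multifocal breasts use an automated any-focus
rule, and all overlaps with IoU in (0, 0.30] are exported for external
review — a pure-threshold replacement for the clinical review of borderline
matches, with an audit trail instead of simulated judgement. FROC curves
sweep the ROI score; at every threshold the curve equals an exhaustive
enumeration oracle in the tests.

Decision rules are **strict-exceed** throughout (`score > threshold` means
recall); this makes recall rates non-increasing in the threshold and
bit-exact reproducible.

## The synthetic cohort generator

The generator replaces restricted programme data and *defines the study
conditions* for every simulation-based test.

**Reader model.** Reader $j$ recalls a case when
$\sqrt{\rho}\,w + \sqrt{1-\rho}\,\varepsilon < \Phi^{-1}(p_j)$, with a
per-case difficulty effect $w$ shared by both readers and the arbitration
panel. Marginal accuracies are exact by construction; $\rho$ (default 0.4)
is the tetrachoric inter-reader correlation. Per-reader accuracies are
drawn from the configured mean/SD (defaults 0.437 ± 0.05 sensitivity,
0.952 ± 0.010 specificity), and the reader identity is the inference
cluster. The published sources do not report inter-reader correlation;
0.4 is a stated default of this package, chosen as a mid-range value for
experienced readers on a shared case stream, not a reproduced quantity.

**AI score model.** Each breast draws a latent Gaussian (standard normal
for normal tissue, mean $\mu_c$ for the affected side of a class-$c$
cancer, plus any device shift); the case latent is the maximum over imaged
breasts and the score is a monotone logistic transform anchored so the
configured operating point (default 0.5) reproduces the configured
specificity and per-class sensitivities *exactly* — the threshold solves
the unilateral/bilateral mixture in closed form. Class sensitivities come
from an overall target (default 0.541) distributed over outcome classes by
a relative-detectability profile (defaults ≈ 0.91 screen-detected, 0.25
interval, 0.25 next-round), mirroring the observation that cancers missed
by the entire double-read pathway are also hard for AI. Case score equals
the maximum of the breast scores — an assumption the metrics inherit, made
explicit here because published systems do not always state the
aggregation rule.

**Everything else.** Outcome prevalences default to the published
five-service composition (0.76% screen-detected, 0.29% interval, 0.68%
next-round of screened women); eligibility flags (technical recall >
implants > missing views > extra views > size, a fixed, arbitrary
precedence) yield ≈ 92.8% inclusion; device and subgroup mixes, a small
unilateral rate (0.6%, matching the published breast-count deficit),
multifocality at 15%, and candidate ROIs whose IoU against truth boxes is
drawn from a controllable distribution. Distribution shift is injected on
the logit score scale per device stratum, leaving other strata
bit-identical.

**What the generator does not emulate.** Attributes are independent of
outcome by default (no age–risk gradient); reader behaviour does not drift
over time; arbitration panel accuracy is a configurable model
(default sensitivity 0.60, specificity 0.75 — real panels are not
characterised in the sources); and outcome classes are exogenous draws, so
the match between "screen-detected" and simulated consensus recall is
statistical rather than definitional. Passing tests therefore demonstrate
correctness of the evaluation machinery under a plausible data-generating
process, not clinical performance of any real system.

## Workflow simulation

Routing follows the two published arbitration styles: *discordant-only*
(disagreements arbitrated; concordant recalls go direct to clinic with a
configurable probability, else to arbitration) and *arbitrate-all* (any
flagged case). In the AI arm, AI-eligible episodes consume one human
screening read (the AI replaces the second), ineligible episodes retain
their two-reader workflow. Workload is reported in equivalent reads
(screening + 5 × arbitration, from 132 s arbitration vs 25 s single reads;
supplying inconsistent seconds raises a warning, not an error). Because
only arbitration *counts* are observable retrospectively, detection
outcomes under simulated arbitration are explicitly model-dependent; the
panel model is pluggable (`oracle`, `fixed`, `always_uphold`).

## Operating points and monitoring

`select_op()` scans all observed score thresholds, excludes the degenerate
threshold that recalls nobody, and returns the feasible threshold
maximising sensitivity, tie-breaking toward higher specificity and then the
higher threshold. Tuning/evaluation identifier overlap is a hard error.
Deployed monitoring uses recall-rate proxies (outcomes lag by months): a
trigger fires when AI recall exceeds the first reader's by strictly more
than 2 percentage points — the boundary is exclusive, and implemented with
a 1e-9 tolerance so an exact 2.0-pp gap in floating point does not trigger
— or when the predicted arbitration rate (obtained by routing the window's
decisions through the workflow rules at the candidate threshold, since no
published prediction method exists) reaches 2.5× the human-only rate.
Recalibration requires a minimum window (default 1,000 cases; size, not
calendar time, is the stable criterion), picks the lowest feasible
threshold, is idempotent on an unchanged window, and archives the prior
operating point with its active period.

## Fairness auditing

`subgroup_report()` runs the paired comparison per subgroup level with an
explicit `"missing"` level (never silently dropped), flags subgroups under
50 positives as too small for strong conclusions, and reports zero-positive
sensitivities as undefined. Calibration uses 10 quantile bins per subgroup
by default, summarised by a bin-size-weighted expected-vs-observed gap.
`required_sample_size()` inverts the paired Wald half-width: with typical
reader–AI discordance (default 0.12 among positives), a ±5-point 95%
half-width needs on the order of 150–200 positives, i.e. roughly
10,000–15,000 examinations at screening prevalence — the reason subgroup
fairness cannot be concluded from a few weeks of deployment data.

## Problem sizes and numerical choices in the test suite

Simulation-based tests use cohorts of 50,000–120,000 episodes for
calibration recovery and injected-deficit detection (3-standard-error
bands), 2,000 cohorts of 5,000 cases for the boundary size study, 300
replicates of 500-iteration bootstraps for coverage, and exhaustive
enumeration oracles on fixtures of tens of units; these sizes were chosen
to keep Monte-Carlo error well below the tested tolerances while the whole
suite completes in well under a minute. All randomness is seeded; the
generator restores the caller's RNG state.

## Known limitations

Breast-level inference is provided through case-level bootstrap rather than
a dedicated bivariate model; the arbitration panel model is a stand-in, so
simulated consensus accuracy should not be read as programme performance;
and the generator's subgroup attributes are exchangeable by default, which
makes fairness tests specific to injected effects rather than realistic
demographic structure.
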