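---
title: "Population-correlation selection of prognostic and chemopredictive miRNAs"
author: "mirPopCor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-correlation selection of prognostic and chemopredictive miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Expression cohorts with matched survival are small (tens of patients);
cancer registries are large (tens of thousands) but carry no molecular
profiles. `mirPopCor` implements a linkage between the two through
*composite tumor-progression groups*: every patient — in either cohort —
is assigned a key `T{t}N{n}M{m}G{g}` from their AJCC T, N, M stage and
tumor grade. Patients who share a key are treated as occupying the same
point on a tumor-progression scale, which lets group-level summaries
travel from one cohort to the other:

1. **Cohort screen.** In the expression cohort, each miRNA is tested for
   survival association twice: a univariate Cox proportional-hazards model
   on the continuous expression, and a Kaplan–Meier log-rank scan over
   candidate expression cutoffs between the 5% and 95% expression
   quantiles. A miRNA passes only if both are significant and agree in
   sign (Cox beta < 0 exactly when the over-expression arm survives
   longer).
2. **Group-level regression.** Mean expression per progression group in
   the cohort is regressed (OLS) against the group's restricted mean
   disease-specific survival (RMST, the area under the Kaplan–Meier curve)
   in the registry, across the groups common to both cohorts.
3. **Population re-evaluation.** Each registry patient is imputed their
   progression group's cohort-mean expression, and the Cox and
   Kaplan–Meier models are re-fitted on the registry at scale.

A *prognostic* marker (evaluated on registry patients without
chemotherapy) must be significant and direction-concordant on **all**
layers, including both population models. A *chemopredictive* marker
(evaluated on agent-treated patients) needs the cohort screen, the
regression, and **either** population model; a positive direction (higher
expression, longer survival under the agent) labels it chemo-sensitive,
a negative one chemo-resistant. The direction convention is fixed
package-wide: *positive* = higher expression ↔ longer survival ⇔ Cox
beta < 0 ⇔ regression slope > 0 ⇔ KM direction +1.

```{r}
library(mirPopCor)
cfg <- simulationConfig(seed = 1, nRegistry = 20000, nCohort = 200,
                        nMirna = 10, plantedEffects = c("mir-001" = -1))
registry <- simulateRegistry(cfg)
cohort <- simulateExpressionCohort(cfg)
sel <- selectMarkers(cohort, registry, rule = "prognostic")
sel
markerRecords(sel)
```

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `alpha` | 0.05 | significance level of every layer, uncorrected |
| `baselineHazard` | 0.02 | disease-specific deaths / month at T1 N0 M0 G1 |
| `hazardLoadings` | 0.25 each | log-hazard per unit of (T−1), N, M, (G−1) |
| `censorRate` | 0.01 | independent censoring events / month |
| `otherCauseDeathProb` | 0.2 | deaths relabeled other-cause (censored) |
| `noiseSd` | 0.5 | expression SD around the planted mean structure |
| `minGroupRegistry` | 10 | registry members for a group to enter linkage |
| `minGroupCohort` | 1 | cohort members for a group to enter linkage |
| `qLo`, `qHi`, `nGrid` | 0.05, 0.95, 20 | cutoff-scan quantile window / grid |
| `minPerSide` | 3 | smallest arm allowed at a scan cutoff |
| dependency `threshold` | −0.5 | score at or below marks a significant effect |

Significance is deliberately uncorrected within each layer, matching the
method's design: false discovery is controlled by the *conjunction* of
layers and by external validation, not by multiplicity adjustment. Every
scan reports `n_cutoffs_tested` so users can apply their own correction.

The severity score used by the generator is `(T-1) + N + M + (G-1)` —
the simplest monotone composite consistent with ordering progression
groups; the hazard loadings are configurable per component.

## What the synthetic module emulates — and what it does not

`simulateRegistry()` and `simulateExpressionCohort()` draw T, N and grade
from categorical distributions shaped like a lung squamous carcinoma
registry population (grade ≈ 4.5% / 41.5% / 54%); M is fixed at 0 because
metastatic groups are absent from the cohort–registry intersection in
practice. Survival is exponential (Weibull via `weibullShape`) with a
log-linear hazard in the progression components; disease-specific
analysis censors other-cause deaths. Planted miRNAs have mean expression
proportional to severity; nulls are pure noise. `simulateClaims()` plants
agent procedure codes with lung-diagnosis codes plus distractor claims
that defeat naive procedure-only matching. `simulateCellPanel()` and
`simulateDependencyScreens()` provide drug-activity and knockout/knockdown
matrices with known planted structure.

Real data differ in ways the generator does not attempt: expression is
not Gaussian around a linear severity trend, stage and grade are
correlated with age and treatment choice (confounding by indication),
registry staging migrates across eras, and claims histories are far
noisier than a three-column table. Passing tests therefore demonstrate
that the machinery is correct and calibrated — not that the selection
rule has any particular operating characteristic on real cohorts.

Every generator derives its RNG stream from `(seed, generator name)`, so
modules are decoupled: changing the cohort size never perturbs the
registry draw, and reruns are bit-identical.

## Numerical and design choices

* **RMST truncation.** The KM area is undefined beyond follow-up when the
  curve does not reach zero, so `rmst()` integrates to
  `min(tau, max follow-up)` and `groupSurvivalProfile()` uses one
  stratum-wide `tau` (the subset's maximum observed time) so group areas
  are comparable.
* **Ties.** Cox fits use Breslow tie handling (Newton iteration,
  tolerance 1e-9, max 100 iterations, via the survival package); with
  continuous simulated times ties are rare. Efron is available.
* **Cutoff scan.** Candidates are the distinct expression values inside
  the quantile window, capped at `nGrid` evenly spaced quantiles
  (`useAllValues = TRUE` scans every value). Ties on the minimum p keep
  the smallest cutoff. Cutoffs leaving fewer than `minPerSide`
  observations on a side are skipped; if all are skipped, the scan
  errors rather than fabricating a split.
* **Population KM split.** The imputed covariate takes at most one value
  per group, so the quantile scan degenerates; the default splits at the
  median imputed value (with a balanced fallback when the median equals
  the maximum), and `scanPopulationKm = TRUE` scans the distinct imputed
  values instead.
* **Prognostic rule variant.** The population stage of the prognostic
  rule requires both Cox and KM by default
  (`requireBothPopulation = TRUE` in `selectPrognostic()`); the
  either-model reading is the chemopredictive rule and is available as a
  switch.
* **Trichotomization.** Dose-bound overrides are applied before the
  mean ± 0.5 SD split, and overridden lines are excluded from the
  remainder's mean/SD (a switch includes them). Values exactly at a
  threshold are *partial*: the extreme classes are strict. The labels are
  invariant under translation and positive scaling.
* **Dependency threshold.** Scores ≤ −0.5 (boundary included) count as a
  significant proliferation effect; essentiality fractions are computed
  over non-missing lines with the denominator reported.
* **Expression scale.** Cohort group means are computed on the expression
  scale provided (log-like in the synthetic data); fold changes in
  `differentialExpression()` back-transform declared log scales before
  the ratio.
* **Treatment strata.** `surgery_only` excludes any radiation
  (preoperative or otherwise); `radiation_only` excludes any surgery;
  `surgery_and_radiation` requires both flags; `any_treatment` is the
  union view. The strata are analysis views, not a partition.

## Calibration, power and the cost of conjunctive selection

The test suite and `scripts/acceptance.R` exercise the pipeline at the
scale the method is meant for: a 200-sample cohort linked to a
20,000-patient registry, with 100 seeds for power (a planted protective
miRNA with slope −1 per severity unit and noise SD 0.5 is recovered with
its direction in essentially every seed) and 50 seeds of 300-null-miRNA
runs for the null control. These sizes are the package's chosen study
conditions; smaller fixtures are used where a property does not need
scale.

Two calibration facts are worth understanding before trusting any
selection list. First, the cutoff scan reports an *uncorrected minimum*
p-value over its grid and is therefore anti-conservative by construction
(its null rate is far above the nominal 5%; the suite asserts this
rather than hiding it). Second, the three layers are positively
dependent: cohort survival and registry survival are both driven by the
same progression components, so a null miRNA whose noise happens to
align with severity tends to pass several layers at once. The per-miRNA
composite null selection rate is far below `alpha` but not zero — the
acceptance script recomputes it (`null_selection_rate_per_mirna`) on
every run. With hundreds of screened features, occasional null
selections are expected; the method's false-discovery control is the
conjunction *plus external validation*, and users should treat a
selection list as candidates for validation engines
(`nci60Regression()`, `classifyDrugResponse()` +
`differentialExpression()`, dependency screening), not as confirmed
markers.

## Known limitations

* No multivariable Cox, time-varying covariates, or competing-risks
  estimators: disease-specific survival is handled upstream by censoring
  other-cause deaths.
* Grade must already be numeric; mapping descriptive differentiation
  terms is out of scope.
* The claims model is a three-column abstraction, not a Medicare claims
  format.
* No dose–response fitting: IC50/EC50 values are inputs.
* No enrichment/network analysis downstream of the dependency screen.
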