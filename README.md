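# mirPopCor

Selection of prognostic and chemopredictive miRNA biomarkers by linking a
small tumor expression cohort to a large cancer-registry cohort through
composite tumor-progression groups.

## The problem

Expression cohorts with survival follow-up are small — often under a
hundred patients — while cancer registries hold tens of thousands of
patients with staging, treatment and disease-specific survival but no
molecular profiles. `mirPopCor` bridges the two for non-small-cell lung
cancer–style data: every patient in either cohort is assigned a composite
tumor-progression key `T{t}N{n}M{m}G{g}` from AJCC T/N/M stage and tumor
grade, and group-level summaries are carried across the link.

For each miRNA the selection runs three layers:

1. **Cohort screen** — univariate Cox PH fit (Breslow ties, Newton
   iteration) *and* a Kaplan–Meier log-rank scan over expression cutoffs
   between the 5% and 95% quantiles; both must be significant with
   agreeing sign (β < 0 ⇔ the over-expression arm survives longer).
2. **Group-level regression** — OLS of the registry groups' restricted
   mean survival (RMST = area under the KM curve, one stratum-wide
   truncation τ) on the cohort's group-mean expression across the shared
   progression groups.
3. **Population re-evaluation** — each registry patient is imputed their
   group's cohort-mean expression; Cox and KM (median split) are
   re-fitted on the registry.

A **prognostic** marker (no-chemotherapy registry subset) needs all
layers significant and direction-concordant, including *both* population
models; a **chemopredictive** marker (agent-treated subset) needs the
cohort screen, the regression, and *either* population model — positive
direction ⇒ chemo-sensitive, negative ⇒ chemo-resistant.

Around the core, the package ships the validation engines the method
relies on — cell-panel expression-vs-activity regression, drug-response
trichotomization at mean ± 0.5 SD with dose-bound overrides,
resistant-vs-sensitive differential expression with fold change, and
CRISPR/RNAi dependency-score normalization and essentiality-fraction
screening — plus a synthetic-data module that generates registry,
cohort, claims, cell-panel and dependency inputs with known planted
structure, because the real registry data are license-restricted.

## Worked example

```r
library(mirPopCor)

cfg <- simulationConfig(seed = 11, nRegistry = 4000, nCohort = 120,
                        nMirna = 4, plantedEffects = c("mir-001" = -1))
registry <- simulateRegistry(cfg)
cohort   <- simulateExpressionCohort(cfg)
sel <- selectMarkers(cohort, registry, rule = "prognostic")
sel
#> MarkerSelection (prognostic) stratum=all agent=none
#>   4 miRNAs screened over 27 common progression groups; alpha=0.05
#>   selected: mir-001

markerRecords(sel)[, c("mirna", "cohort_cox_p", "reg_p", "pop_cox_p",
                       "verdict", "direction")]
#>     mirna cohort_cox_p        reg_p    pop_cox_p             verdict direction
#> 1 mir-001  0.002031698 4.289437e-11 1.768393e-44 prognostic_selected  positive
#> 2 mir-002  0.458990064           NA           NA            rejected      <NA>
#> 3 mir-003  0.135105017           NA           NA            rejected      <NA>
#> 4 mir-004  0.330112252           NA           NA            rejected      <NA>
```

`mir-001` was planted with slope −1 per severity unit: low expression
marks advanced disease, so high expression is protective — it is selected
with direction `positive` (higher expression ↔ longer survival; Cox
β < 0; regression slope > 0). The three null miRNAs fail the cohort
screen and the downstream layers are never computed for them.

`runPipeline(cfg, agents = c("any", "paclitaxel"), outDir = "out")` chains
simulate → claims-based treatment flags → prognostic + chemopredictive
selection and writes TSV tables plus a JSON run summary;
`inst/scripts/run-pipeline.R` wraps it for the shell.

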