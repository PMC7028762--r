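# prepostCEA

Descriptive pre–post cost-utility analysis of psychosocial care programmes
from a payer perspective, built for evaluations in which an outreach,
counseling or coordination service is assessed by comparing each client's
service costs and quality of life in the year before first contact with the
year under the programme — without a randomized control group.

The package is aimed at health-economics analysts who have (a) per-client
service-utilization records (e.g. from the Client Sociodemographic and
Service Receipt Inventory, CSSRI), (b) a unit-cost table (EUR per inpatient
day, per visit, per therapy unit, …), and (c) SF-12 quality-of-life
interviews at baseline and at 3-, 6- and 12-month follow-ups. Because such
client-level data are typically confidential, the package also ships a
calibrated synthetic-cohort simulator so every stage of the pipeline can be
run, tested and benchmarked end to end without any real data.

## What it computes

**Costs.** Reported utilization is multiplied by unit-cost assumptions and
aggregated per cost item and 12-month window into users, mean cost per user,
mean cost per client (with normal-approximation 95% CIs, `mean ± 1.96·SE`),
and totals. The 6-month pre-baseline survey window is annualized (×2).
Missing follow-up intervals are completed by carrying the client's last
complete interval forward, rescaled to the target interval's length (LOCF).
A flat per-client counseling fee represents the programme's own cost.

**Effects.** SF-12 responses are scored into PCS/MCS component summaries
(norm-based regression weights, population mean 50), classified into SF-6D
health states, and valued with an additive-decrement preference tariff:

    u(s) = 1 − Σ_d c_d(s_d) − c_most · 1{any dimension most severe}

Quality-adjusted life-years for the study year are the area under the
utility–time curve with linear interpolation between interviews (trapezoid
rule over nominal times 0, 0.25, 0.5, 1 years); the pre-period QALY assumes
the baseline utility was stable over the previous year. Missing utilities
are LOCF-imputed.

**Cost-effectiveness.** Per client, Δcost = cost_post − cost_pre and
ΔQALY = QALY_post − QALY_pre. The cohort means are classified on the
cost-effectiveness plane (dominant / ICER = Δcost/ΔQALY / dominated), and a
client-level nonparametric bootstrap (n-out-of-n, pairs kept intact,
B = 1000 by default) yields the scatter of the plane and the
cost-effectiveness acceptability curve: for each willingness-to-pay λ, the
fraction of replicates with positive net monetary benefit
λ·ΔQALY − ΔCost > 0.

Note on the shipped SF-6D tariff: the licensed Sheffield preference weights
are not redistributable, so the default coefficient file is a clearly
labelled synthetic stand-in with the published model's structure (monotone
decrements, floor 0.345). The loader accepts any licensed coefficient file
with the same layout.

## Worked example

```r
library(prepostCEA)

spec <- default_cohort_spec()          # calibrated 85-client cohort
cfg  <- run_config(output_dir = "demo", cohort = spec, B = 1000, seed = 1)
res  <- run_pipeline(cfg)
summary(res$cea)
```

```
Pre-post cost-effectiveness analysis
  n = 85 clients, B = 1000 bootstrap replicates (seed 1)
  mean Δcost: -3,537 EUR; mean ΔQALY: 0.0341
  quadrant: dominant
  bootstrap 2.5-97.5% Δcost: [-6,434, -1,016] EUR
  bootstrap 2.5-97.5% ΔQALY: [0.0123, 0.0571]
  P(dominant quadrant): 0.999
  P(cost-effective at 50,000 EUR/QALY): 1.000
```

The cohort mean cost difference is negative while the mean QALY difference
is positive, so the simulated programme sits in the dominant (south-east)
quadrant of the cost-effectiveness plane — cheaper and more effective — and
no ICER is reported. Nearly all bootstrap replicates agree, and the
acceptability curve is ≈ 1 across the willingness-to-pay grid. Per-cohort
results vary seed to seed: single 85-client cohorts have heavily skewed
inpatient costs, so individual simulations can land in the north-east
quadrant with a finite ICER.

`run_pipeline()` writes the full report bundle into `output_dir`: the
simulated cohort (`clients.csv`, `utilization.csv`, `sf12_responses.csv`),
`cost_summary.csv` (per-user / per-client / total layout with CIs and the
post-minus-pre difference column), `qol_summary.csv` (PCS, MCS and utility
by visit), `qaly.csv`, `ce_plane.csv`, `ceac.csv`, `ce_summary.json` and a
deterministic `run_log.txt` (seed, config hash, coefficient-file
checksums). The same stages are exported individually
(`cost_records()`, `impute_cost_locf()`, `aggregate_costs()`,
`score_sf12()`, `sf12_to_sf6d()`, `sf6d_utility()`, `qaly_pairs()`,
`client_deltas()`, `cea()`, …) for analyses that start from existing CSVs.

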