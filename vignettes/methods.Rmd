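---
title: "Methods: pre-post cost-utility analysis of psychosocial care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-post cost-utility analysis of psychosocial care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepostCEA)
```

## The design and its assumptions

`prepostCEA` implements a descriptive, uncontrolled pre–post cost-utility
analysis from a payer perspective. Each client serves as their own control:
the 12 months under a psychosocial counseling programme are compared with
the 12 months before first contact. Two structural assumptions carry the
whole design and should be kept in mind when interpreting any output:

* **Pre-period extrapolation.** Utilization is surveyed retrospectively for
  the 6 months before baseline and doubled to a 12-month window
  (`annualize_pre()`). This assumes the half-year before first contact is
  representative of the full prior year; for clients who sought help during
  an acute crisis it may overstate the stable pre-period cost level.
* **Stable pre-period utility.** The pre-period QALY equals the baseline
  utility (`qaly_pre()`), i.e. health-related quality of life is assumed
  flat during the year before first contact. Together with
  regression-to-the-mean this tends to favour the intervention; the package
  computes the quantity as defined and leaves the causal caveats to the
  analyst.

No discounting and no half-cycle correction are applied: the horizon is a
single year on each side.

## Costing

`cost_records()` multiplies reported units (days, visits, therapy units) by
the unit-cost table. Prices are configuration data, shipped as a CSV preset
(psychiatric inpatient day 386 EUR, somatic inpatient day 576 EUR, day-care
day 168 EUR, psychiatrist visit 45 EUR, GP visit 20 EUR, sheltered
workplace day 48 EUR, occupational therapy unit 38 EUR, physical therapy
unit 16 EUR, day-structuring unit 33 EUR, contact/counseling-center visit
29 EUR, home-nursing visit 22 EUR, police contact 62 EUR). Spend without a
natural per-unit price — medication, miscellaneous complementary services,
other contacts — enters as direct EUR amounts under a category label.
Currency is held in double precision throughout; rounding to whole EUR
happens only in the print method.

The follow-up calendar is fixed by the interview schedule: intervals of 3,
3 and 6 months (baseline→3m→6m→12m). Three choices here were genuinely
open and are the package's own:

* **LOCF length scaling.** When a client's missing follow-up interval is
  completed from their last complete interval, the carried-forward per-item
  costs are rescaled by the interval-length ratio (a 3-month interval
  carried into the final 6-month interval is doubled). Unscaled carrying
  would systematically undercount the final interval, which covers half the
  study year. The carried rows are flagged (`imputed`, `imputed_from`).
* **Clients with no complete follow-up** (baseline interview only) have no
  follow-up interval to carry; their pre-period monthly spending rate is
  carried forward instead, flagged distinctly (`imputed_from = "pre6m"`).
  The alternative — excluding such clients — would silently change the
  denominator of every per-client mean.
* **Confidence intervals** are normal-approximation `mean ± 1.96·SE`
  across the relevant denominator (users or all clients). Symmetric
  intervals can have negative lower bounds for strictly positive costs;
  that is accepted deliberately, as the small-user-count items are so
  skewed that no two-parameter summary is faithful anyway. The per-user CI
  is suppressed when an item has fewer than two users.

`aggregate_costs()` guarantees, by construction and by test, that the
overall row equals the sum of the item rows in every window and that
`total = per_client_mean × n_clients` before display rounding.

## Quality of life and QALYs

SF-12 responses are scored complete-case per visit: any missing item makes
the visit unobserved, which keeps the scoring weights' norm-based
interpretation intact; missing visits are then completed by
last-observation-carried-forward on the utility scale
(`impute_qol_locf()`), never backwards and never at baseline (a missing
baseline is an error, such clients must be excluded upstream).

Component summaries use the public US 1998 SF-12 (version 1) regression
weights, shipped as a versioned CSV with checksum; a national adaptation
with the same layout can be supplied. With the shipped file the best
possible response scores PCS 56.58 / MCS 60.76 and the worst 24.00 / 19.06,
frozen as golden test values.

SF-6D classification follows the published SF-12-variant mapping: six
dimensions (physical functioning, role limitation, social functioning,
pain, mental health, vitality) driven by seven of the twelve items, with
the two middle frequency levels of the six-level items collapsing to one
dimension level. Utilities apply an additive-decrement tariff with a single
extra penalty when any dimension is at its most severe level.

**Tariff provenance.** The licensed Sheffield preference weights cannot be
redistributed, so the shipped tariff file is a synthetic stand-in, labelled
as such in its filename and header. It preserves the published model's
structure — additive, monotone within dimension, worst-state utility
(floor) 0.345, best state exactly 1 — so every structural property the
package tests (bounds, dominance, monotone classification) is meaningful,
but absolute utility levels from the default file should not be quoted as
Sheffield-tariff values. Any licensed coefficient file in the same layout
plugs in via `sf6d_tariff(path)`.

QALYs use the area-under-the-curve construction: linear interpolation
between interviews and exact trapezoid integration over the year,
`qaly_post()`. Nominal visit times (0, 0.25, 0.5, 1 years) are the default;
actual per-client interview dates can be passed via `visit_times`. QALYs
are computed per client and then averaged — with shared nominal times this
coincides with the area under the mean trajectory (tested), but per-client
computation is the general contract. The implementation is validated
against a hand-computed trapezoid oracle and a refinement-invariance
property (inserting an interpolated midpoint changes nothing).

## Cost-effectiveness summary

`cea()` is the package's estimator. Per-client paired differences feed:

* the quadrant/ICER classification (`classify_quadrant()`): dominant
  interventions (cheaper, more effective) report no ICER; a zero mean QALY
  difference leaves the ICER undefined rather than infinite;
* a client-level nonparametric bootstrap, n-out-of-n with replacement,
  keeping each client's (Δcost, ΔQALY) pair intact — resampling clients,
  not cost–effect coordinates, is what preserves the within-client
  correlation, and a regression test verifies that deliberately unpairing
  correlated data visibly changes the acceptability curve;
* the acceptability curve: `P(λ·ΔQALY − ΔCost > 0)` over a default λ grid
  of 0–100,000 EUR/QALY in 1,000 EUR steps. The inequality is strict: a
  net monetary benefit of exactly zero counts as not cost-effective. The
  tie rule matters only on measure-zero events but is stated so results
  are exactly reproducible.

Bootstrap determinism comes from a single recorded seed; R's default
Mersenne-Twister stream is restored after use so `cea()` never perturbs
the caller's RNG state.

## The synthetic cohort: what it emulates, and what not

`default_cohort_spec()` encodes the study conditions the analyses assume:
85 clients, 74.1% female, age 45.7 ± 17.0 truncated to 18.4–77.8 years,
education/living/employment/income mixes typical of a rural psychosocial
clientele, and a per-follow-up dropout probability of 0.0494 chosen so the
expected completer fraction is 0.859 over three visits. Dropout is
independent of health state by default (the mechanism is unknown; the
spec field is a plain probability, so informative dropout can be emulated
by running stratified specs).

Utilization is zero-inflated and overdispersed: per item and window a
client is a non-user with probability `zero_prob`; users draw
negative-binomial counts (gamma amounts for direct-EUR categories) whose
conditional means are set so the *marginal* expected EUR per client matches
the item's calibration target. This reproduces the qualitative signature of
psychosocial service data — most items used by few clients with large
per-user costs (e.g. psychiatric day care: ~5% users, five-figure per-user
annual cost). Item-level EUR targets allocate the per-category margins
(inpatient 2,515 EUR pre / 1,657 post per client, day care 637 / 5,
outpatient 587 / 802, medication 728 / 731, complementary 1,086 / 832,
other 279 / 223; totals 5,832 pre and 4,350 post including the 100 EUR
counseling fee); the split of a category across its items is the package's
choice. Post-window targets are pre-adjusted for the expected cost mass
that baseline-only clients carry forward from the pre period under LOCF,
so the post-LOCF expectation hits the target without bias.

SF-12 responses come from a two-factor latent model: person-level physical
and mental health (person SD 0.8, occasion SD 0.6 on a population scale
where 0 is the general-population mean), fixed monotone item thresholds
set from plausible population prevalences, primary loadings 1.0 with 0.25
cross-loadings (0.6/0.6 for general health). Baseline latent means
(−0.50 physical, −1.507 mental) and per-visit mental drifts (0.454, 0.464,
0.785; physical 0.08, 0.12, 0.16) were fixed once by Monte-Carlo
calibration so the post-LOCF mean utilities track 0.6051, 0.6535, 0.6602,
0.6927 at the four visits — a clientele with markedly impaired mental
health improving substantially more on the mental than the physical
component. Reproducibility uses one master seed with deterministic
per-client substreams, so enlarging a cohort never changes earlier
clients' draws.

What the generator does **not** emulate: diagnoses or clinical narratives;
correlation between utilization and health state (costs and utilities are
independent given the margins, so the synthetic within-client cost–QALY
correlation is near zero — real cohorts are likely negatively correlated);
informative dropout; seasonal or calendar effects; and recall error in the
retrospective interviews. Passing the parameter-recovery tests therefore
shows the pipeline's arithmetic and calibration are right, not that the
generator reproduces any real population's joint distribution.

## Numerical choices and degenerate inputs

* All EUR and utility arithmetic in double precision; no intermediate
  rounding.
* `impute_cost_locf()` is idempotent: a period that already has rows for a
  client is never re-imputed, and a genuinely zero-use observed period is
  distinguished from a missing one by the client's `last_observed_visit`.
* One-client cohorts are legal everywhere: the bootstrap degenerates to
  constant draws, per-user CIs are suppressed.
* Zero utilization means produce an empty utilization table and zero-cost
  summaries rather than errors.
* Spec YAML round-trips with 17 significant digits so a written and
  re-read spec simulates byte-identically.
* Output files contain no wall-clock content, making whole-run outputs
  byte-identical under a fixed seed (tested via md5).

## Problem sizes used by the test suite

Unit tests run on cohorts of 5–85 clients; the exhaustive SF-6D checks
enumerate all 7,500 states; the bootstrap oracle uses 10^5 replicates on a
3-client cohort against exact enumeration of all resamples; the
parameter-recovery test averages 200 simulated 85-client cohorts (the
Monte-Carlo standard error of the mean pre-period cost is then ≈ 70 EUR,
comfortably inside the ±5% band it asserts). The full suite completes in
under a minute on one CPU.

## Known limitations

* The default tariff is a synthetic stand-in (see above); substantive
  utility levels require licensed coefficients.
* Normal-approximation CIs on heavily skewed, zero-inflated cost items are
  descriptive at best; the bootstrap plane is the better uncertainty
  summary.
* The cli layer is R-functional (`run_config()` + `run_pipeline()`);
  there is no shell subcommand interface.
* No probabilistic sensitivity analysis over unit-cost assumptions, and no
  Fieller or percentile-based ICER confidence intervals.
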