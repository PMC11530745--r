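---
title: "Methods: trends in gestational age at live birth"
author: "gestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trends in gestational age at live birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestage)
```

## The analysis this package implements

National maternity registries record, for every pregnancy ending in a live
birth, the completed weeks of gestation at delivery alongside maternal and
obstetric details. The standard surveillance analysis of such data asks how
the distribution of gestational age at birth is changing over calendar time:
what share of births is preterm (<37 completed weeks), term (37–41 weeks)
and post-term (≥42 weeks); how preterm births split into moderate to late
(32–36 weeks), very (28–31 weeks) and extremely (<28 weeks) preterm; whether
a preterm birth began spontaneously or was provider-initiated; and how these
shares differ by maternal age and by area deprivation.

`gestage` implements that analysis end to end as a tested pipeline:

1. **records** — pregnancy-level validation and CSV input/output
   (`birth_records()`, `read_records()`, `write_records()`), plus a synthetic
   registry-like cohort generator (`synthetic_config()`,
   `generate_records()`).
2. **classify** — gestational categorisation (`categorize_gestation()`) and
   the hierarchical onset-of-labour rules (`assign_onset()`,
   `match_pprom()`, `onset_rules()`).
3. **aggregate** — year × stratum × category count tables with explicit
   denominator handling (`count_births()`, `percentages()`,
   `yearly_count_table()`, `onset_count_table()`).
4. **trends** — endpoint differences with confidence intervals and the
   per-year odds ratio from aggregate birth-weighted logistic regression
   (`absolute_difference()`, `relative_difference()`,
   `relative_difference_ci()`, `fit_binomial_trend()`, `gestage_trend()`).
5. **report** — the full pipeline with tidy CSV outputs and a run manifest
   (`run_config()`, `run_pipeline()`, `gap_table()`).

The package's interface is the classic R modelling idiom rather than a shell
tool: `fit_binomial_trend()` and `gestage_trend()` return classed objects
with `print`, `summary`, `coef`, `vcov`, `confint`, `predict`, `fitted`,
`residuals`, `simulate` and `plot` methods, and `run_pipeline()` drives the
whole analysis from a single configuration object. Users script it from R;
there is deliberately no shell subcommand layer.

## Units of analysis and denominators

A record is one *pregnancy*, never one baby: a multiple pregnancy with at
least one live-born baby is a single record classed as `multiple`, and all
analyses run separately for singleton and multiple births. Unknown values
are a distinct state (`NA` internally, an empty cell on CSV), never a
numeric sentinel, so unknowns can never leak into arithmetic.

Registry percentages follow strict denominator conventions, which the
`count_table` object makes explicit by carrying four denominators per
year × stratum:

* `total` — all records (including unknown gestation);
* `known_gestation` — the denominator for unstratified and week-by-week
  percentages; records with unknown gestation are excluded from category
  counts but retained in `total`;
* `known_gestation_and_stratum` — for age- and deprivation-stratified
  percentages, records must additionally have a known stratum; the
  unknown-stratum residue is kept as its own stratum so stratified tables
  still sum exactly to the unstratified ones;
* `known_onset` — onset-of-labour shares are computed among preterm births
  whose onset could be assigned; unassignable records stay in the preterm
  totals but in neither onset column.

Every table build asserts conservation (category counts sum to the
known-gestation denominator per year); the pipeline re-checks it in the run
manifest.

Displayed percentages are rounded *half away from zero* to one decimal
place (`round_half_up()`), the convention of published registry tables. All
downstream statistics are computed on unrounded proportions: rounding first
would, for example, turn the post-term relative difference of −42.26% into
−42.9% ((1.6 − 2.8)/2.8), visibly inconsistent with the unrounded value.

## Gestational categories and the onset-of-labour hierarchy

`categorize_gestation()` partitions the inclusion window of 22–44 completed
weeks (22+0 to 44+6): every integer week maps to exactly one category, and
weeks outside the window are a domain error — window filtering is an
upstream inclusion decision, not something to silently absorb.

Onset of labour is defined for preterm births only and is assigned by a
hierarchy of seven rules applied in order, first match wins:

| Group | P-PROM code | Induction | Mode of delivery | Duration | Onset |
|---|---|---|---|---|---|
| 1 | yes | any | any | any | spontaneous (P-PROM) |
| 2 | no | yes | any | any | provider-initiated (IoL) |
| 3 | no | no/unknown | any vaginal | any | spontaneous |
| 4 | no | no/unknown | any CS | 0 | provider-initiated (pre-labour CS) |
| 5 | no | no/unknown | any CS | >0 | spontaneous |
| 6 | no | no/unknown | elective CS | unknown | provider-initiated (pre-labour CS) |
| 7 | no | no/unknown | emergency CS | unknown | spontaneous |

Implementation decisions worth stating:

* P-PROM matching is prefix-based on the normalised ICD-10 code ("O42"
  after upper-casing and stripping dots), in any diagnostic position — the
  rule names a code *range*, O42.0–O42.9, not a position.
* A recorded labour duration of zero is evidence of a pre-labour caesarean;
  an *unknown* duration is a different state routed to groups 6/7. The two
  must never be conflated.
* A caesarean of unspecified type with unknown duration matches neither
  group 6 nor 7 and falls through to an unknown onset: the elective/
  emergency distinction is the information those rules require, and
  guessing would fabricate a rule.
* A vaginal delivery with *unknown* induction status reaches group 3:
  groups 3–7 require "no or unknown" induction, whereas group 2 requires an
  affirmative yes.

Records matching no rule receive `onset = unknown`, `rule_group = NA`; in
real registry data this residue is a handful of records per decade, and the
aggregation keeps them in preterm totals while excluding them from onset
shares.

## Trend statistics

For each outcome category the trend summary (`gestage_trend()`) reports the
quantities of the standard published trend table:

* **Absolute difference** — endpoint minus baseline percentage,
  `100 (p_end − p_start)`, with the independent-samples Wald interval
  `± z √(p₀(1−p₀)/n₀ + p₁(1−p₁)/n₁) × 100`.
* **Relative difference** — `100 (p_end − p_start)/p_start`, on unrounded
  proportions. Its interval is the delta-method interval for the ratio
  r = p₁/p₀: Var(r) ≈ r²(cv₀² + cv₁²) with cvᵢ² = (1−pᵢ)/(nᵢpᵢ), giving
  `100(r−1) ± z·100·√Var(r)`. This symmetric form is validated in the test
  suite against a 100,000-replicate parametric bootstrap (endpoint agreement
  within 0.1 percentage points at registry-scale n). Published tables
  sometimes print asymmetric intervals for this quantity derived from other
  approximations; those are not reproduced and not asserted.
* **Per-year odds ratio** — from an aggregate, univariate logistic
  regression of yearly events/trials counts on calendar year,
  `logit(p_year) = β₀ + β₁·year`, reported as exp(β₁) with the Wald interval
  exp(β₁ ± z·SE). The binomial events/trials likelihood is *identical* to
  the individual-level Bernoulli likelihood, which is the precise sense in
  which the fit is "weighted by the number of births in each year". The
  test suite checks this equivalence against an expanded one-row-per-birth
  `glm()` fit and against the closed-form two-year solution
  (p₀ = 0.1, p₁ = 0.2 one year apart ⇒ OR = (0.2/0.8)/(0.1/0.9) = 2.25,
  exactly, since two points saturate the model).

`fit_binomial_trend()` is fitted by iteratively reweighted least squares,
authored in this package rather than delegated, so that the estimator under
test is independent of the `glm()` oracle used to validate it. Numerical
choices: the year covariate is centred internally for conditioning (the
slope is invariant and the intercept is mapped back to the calendar scale);
iteration starts from the empirical logit of shrunk proportions
(y + ½)/(n + 1); convergence requires the largest absolute coefficient
update to fall below 1e-10 within 50 iterations. Degenerate inputs — zero
events (or zero non-events) in every year, complete separation, singular
normal equations, fewer than two distinct years — raise classed errors;
there are no silent partial results. Odds ratios are displayed rounded half
away from zero to 2 decimal places; year enters in calendar units and the
OR is per one-year increment. The per-category odds ratios are deliberately
unadjusted and no multiplicity correction is applied — the output manifest
says so — matching surveillance practice of reporting each category's crude
trend.

Choices that were genuinely open: Wald rather than profile-likelihood
intervals throughout (matching the symmetric intervals of published trend
tables, and exact enough at registry-scale counts); raw counts rather than
re-derived rounded percentages as the regression input (more information,
and it reproduces published odds ratios); endpoint differences use the
first and last observed years by default but accept any pair.

## The synthetic cohort generator

Real registry extracts are not distributable, so the generator provides a
cohort with the same statistical skeleton for development, testing and
worked examples. Its defaults are fixed study conditions, not tuning knobs:

* 15 years (2005–2019), 50,000 singleton records per year, 1.5% of records
  multiple pregnancies;
* preterm risk `logit P = a + b (year − midpoint)` with a = logit(0.064)
  and b = log(1.01) — the overall preterm level and fitted per-year odds
  ratio of recent national data; the midpoint reference decouples intercept
  and slope, and the odds ratio is invariant to the centring;
* preterm sub-category split 0.833 / 0.110 / 0.057 (moderate-late / very /
  extremely); post-term among non-preterm singletons logit(0.0256) falling
  by log(0.95) per year;
* maternal-age and deprivation mixing distributions with additive log-odds
  offsets reproducing the U-shaped age profile and the deprivation gradient
  in preterm risk; multiples receive an offset calibrated so ~59% are
  preterm;
* an onset mixture P(spontaneous | preterm, sub-category) of 0.601 / 0.582
  / 0.657, shifted for multiples to ~0.43; within spontaneous onsets a
  P-PROM share of 1/3, and within provider-initiated onsets an induction
  share of 0.45 — plausible clinical splits chosen once, as the registry
  aggregates do not publish them;
* per-field missingness well under 0.5% for gestation, maternal age and
  deprivation quintile, mirroring the near-complete source fields.

The generator draws the onset *mechanism* first and then writes it into the
concrete fields the classifier reads (an O42.x code for P-PROM, the
induction flag, mode of delivery, and labour duration — including the
structurally-unknown durations that exercise rules 6 and 7), so
`assign_onset()` recovers the configured mixture exactly in expectation and
every rule group is reachable. Completed weeks are drawn within each
category from a configurable discrete distribution whose default is the
empirical single-week shape of a recent national singleton year.

What the generator does **not** emulate — and therefore what passing tests
on synthetic data cannot show about real data: the observed *U-shaped*
(non-monotone) year trend, since the generative trend is logit-linear; any
real correlation between maternal age and deprivation; secular drift in
the age and deprivation distributions; gestation-week shape differences
between singletons and multiples; and per-baby outcomes (birthweight,
mortality), which are out of scope. Tests of *estimator correctness*
(parameter recovery, conservation, classification) are unaffected by these
simplifications; claims about real Scottish trends rest on the published
aggregate tables shipped in `inst/extdata`, not on the generator.

A fixed seed yields a byte-identical cohort, and generation restores the
caller's RNG state.

## Problem sizes used in the shipped tests

The package's own test suite runs the full pipeline on cohorts of a few
thousand records, validates the bootstrap-oracle comparison with 100,000
replicates, and checks parameter recovery of the generative year slope with
20 replicate cohorts of 15 years × 5,000 births (the fitted mean log-odds
slope must lie within 3 Monte-Carlo standard errors of the generative
value — a self-calibrating band, since the Monte-Carlo error is estimated
from the same replicates). These sizes were chosen as the smallest at which
each check is statistically sharp; all conformance checks against the
published aggregate tables are exact desk-scale computations and run in
milliseconds.

## Known limitations

* Single linear-logit trend per category: no changepoint or joinpoint
  modelling, although real series are visibly non-linear within the period.
* No individual-level or multivariable modelling — the inputs are
  aggregate counts, so confounding between age, deprivation and year
  cannot be adjusted away here.
* No stillbirth competing-risk handling; denominators are live births.
* Deprivation quintiles are taken as recorded; deriving them from
  postcodes is out of scope, as is any ethnicity analysis.
* The delta-method relative-difference interval is first-order; at very
  small baseline proportions (p₀n₀ below ~30) a bootstrap or profile
  interval would be preferable.
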