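---
title: "Modelling incidental soil ingestion doses from meso-activity questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling incidental soil ingestion doses from meso-activity questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mesodose)
```

## The problem

Fruit and vegetable growers spend long hours in direct, intentional
contact with soil, yet the soil-ingestion defaults used in risk
assessment are daily, whole-population rates: the same milligrams per
day whether someone weeds for two hours or prepares beds for twelve.
`mesodose` implements a time-activity approach to incidental soil
ingestion built on *meso-activities* — six named agricultural tasks
(bed preparation, planting seeds, transplanting, irrigation, weeding,
harvesting) at a resolution between the whole workday and individual
hand-to-mouth micro-activities.  A seasonal questionnaire supplies, per
grower, the frequency (days) and duration (hours) of on-site work and of
each task, plus the self-reported fraction of task time with hands in
soil.  From these the package derives exposure factors and estimates
average daily doses (ADD, mg contaminant/kg body weight/day) of a
hypothetical soil contaminant under three progressively finer models.

## The three dose models

All three share the standard intake equation

$$ADD = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}$$

with concentration $C$ (default 400 mg/kg), ingestion rate $IR$
(converted from mg to kg of soil by the single factor $10^{-6}$,
applied exactly once inside the dose functions), exposure frequency
$EF$, exposure duration $ED$ (1 month), body weight $BW$ and averaging
time $AT$.  A month is 4.35 weeks throughout, hence 730.8 h
(= 4.35 × 7 × 24).

**Method 1 — daily rate** (`add_method1()`).  $IR$ = 378 mg/day, a
high-end (95th-percentile) modelled soil + dust rate for a high-contact
scenario; $EF$ = days/week on-site × 4.35; $AT$ = 30.5 days.  The
30.5-day averaging time is the convention printed for the daily-rate
model even though 4.35 × 7 = 30.45; the package carries both constants
verbatim (`time_constants()`) and does not reconcile them.

**Method 2 — hourly rates** (`add_method2()`).  Working (outdoor) hours
get 362/8 = 45.25 mg/h; all remaining hours of the 730.8-h month are
assumed indoors at the dust rate 22/16 = 1.375 mg/h (displayed 1.38).
The indoor exposure frequency is defined as the exact complement
`730.8 − outdoor hours`, so outdoor hours above 730.8 are an error, not
a clamp.  Hourly doses are multiplied by 24 to convert an average
hourly dose to an average daily dose.

**Method 3 — hourly task-specific rates** (`add_method3()`).  Each
task's rate is the 45.25 mg/h baseline times a scaling factor assigned
from the questionnaire's mean soil-contact fraction for that task:
doubled (2.0) for high-contact tasks, maintained (1.0) for mid-contact,
halved (0.5) for low-contact.  With the questionnaire means
(transplanting 0.87, weeding 0.72, planting seeds 0.49, bed preparation
0.41, harvesting 0.35, irrigation 0.08) the assignment is
{2, 2, 1, 1, 0.5, 0.5}, i.e. task rates 90.5, 90.5, 45.25, 45.25,
22.625, 22.625 mg/h.  Hours not accounted for by the six tasks are
assumed indoors at 1.375 mg/h.  Because growers may report concurrent
tasks, task hours can sum above 730.8; the indoor complement is then
clamped at zero and the result flagged `indoor_hours_clamped` —
clamping preserves non-negativity of dose where the complement
definition would otherwise go negative.

```{r}
rates <- build_rate_set()
rates
```

### Scaling thresholds

The original assignment of scaling factors was professional judgment;
no cut-points were published.  `scaling_factor_from_contact()` fixes
them at *double at mean contact ≥ 0.60, halve below 0.40, maintain
between* — the unique round-number banding that reproduces all six
published assignments — and exposes them as an argument, since other
judgments are defensible.

### Rounding

Internal arithmetic never rounds: method-3 doses use 22.625 and 1.375,
not the displayed 22.63/1.38 (this moves downstream digits at the third
decimal).  `display_round()` provides the half-up convention used when
rates are printed (base R's `round()` is half-even and would display
22.625 as 22.62).

### Body weight

Empirical estimation uses the median body weight for the grower's sex
and age bracket, overridden by a reported weight when present
(`body_weight_for()`).  The sex × bracket medians that the original
analysis drew from a reference handbook are not published, so the
shipped `generate_bodyweight_table("median_lookup")` is a clearly
documented synthetic placeholder; replace it with handbook values for a
faithful reanalysis of real data.

## Exposure factors and reliability

`exposure_factors()` returns, per grower-season, days/month and
hours/month on-site, total task hours/month, and the *reliability
difference* — on-site hours minus the sum of task hours.  A positive
difference is on-site time spent outside the six tasks; a negative one
indicates concurrent tasks.  Mean contact fractions
(`mean_contact_fraction()`) are computed over engaged growers only
(days/month > 0) and pooled across seasons, because one scaling factor
per task is used for all seasons; a per-season breakdown is available
via `by_season = TRUE` but is not the default.

## Monte Carlo simulation

`run_simulation()` draws a hypothetical population (default n = 5000)
for one season and one method.  Per draw: a body weight sampled from a
population-weighted table (empirical weighted sampling, no smoothing);
the method's exposure factor bootstrapped uniformly with replacement
from the empirical pool of questionnaire values for that season
(`factor_pools()`); and, for method 3, a per-task rate multiplier drawn
uniformly on `scaling ± 0.2` (a doubled task samples 1.8–2.2 × the
baseline rate).  Zeros are kept in the pools by default so the
simulated population reflects engagement prevalence; set
`include_zeros = FALSE` to simulate engaged growers only.

Design choices worth knowing:

* **Independence across tasks.**  Method-3 pools are sampled
  independently per task, which discards within-grower correlation
  between tasks; a grower who works long hours tends to do so across
  several tasks, so simulated totals are somewhat less dispersed than a
  row-bootstrap would give.  This mirrors the per-task sampling design
  the method is based on and is a documented limitation.
* **Randomness.**  One base-R generator is seeded once per run from
  `config$seed` and consumed in a fixed, vectorised order (body
  weights, then factors, then rates), so an identical configuration
  reproduces bit-identical draws.  Counter-based per-draw substreams
  were considered and rejected: base R has no cheap mechanism for them
  and the vectorised single-stream design already guarantees
  reproducibility (tested byte-for-byte).
* **Convergence checks.**  On fixtures with small pools the simulated
  mean is tested against a brute-force enumeration of every
  pool × body-weight combination (with the uniform rate multiplier
  entering through its midpoint), within three Monte Carlo standard
  errors at 100 000 draws; degenerate configurations (single-value
  pools, zero half-width) must collapse to the empirical dose exactly.

## The synthetic cohort generator

Real questionnaire data cannot ship with the package, so
`generate_cohort()` produces cohorts with the *structure* the pipeline
expects and the qualitative features the methods rely on.  Per
grower-season it draws on-site days/week and hours/day from truncated
lognormals whose seasonal means (days/week, hours/day): spring (5, 7),
summer (5.5, 8.5), fall (4.5, 5.5), winter (3.5, 5) — chosen once to
anchor mean on-site hours/month near 205 in summer and 77 in winter
with the summer > spring > fall > winter ordering.  Total task time is
the on-site hours times `1 − f`, where `f` is a Beta-distributed
unaccounted-time fraction (mean 0.30); with probability 0.29 a
grower-season instead gets `f < 0`, making task hours exceed on-site
hours (concurrent tasks), so roughly 70% of reliability differences
come out positive.  The total is split across engaged tasks
(season-dependent engagement probability) with Dirichlet-style gamma
weights and re-expressed as days/month × hours/day exactly.  Contact
fractions are Beta draws with the published task means and
concentration 8 (SD ≈ 0.1–0.17, a plausible between-grower spread).

What the generator does **not** emulate: respondent attrition (every
synthetic grower answers all four seasons), within-grower correlation
of contact fractions across seasons, reporting heaping (real answers
cluster on round numbers), and any individual-level resemblance to the
deposited study data.  Passing tests on synthetic cohorts therefore
demonstrate correctness of the *pipeline arithmetic and its qualitative
behaviour* under realistic structure — not distributional fidelity to
the field data.

With the default spec the generated cohorts reproduce, and the test
suite asserts: recovery of the per-activity contact means within
±0.03 (n = 500); the scaling-factor assignment {2, 2, 1, 1, 0.5, 0.5}
from the recovered means (checked at n = 2000, because the
bed-preparation target 0.41 lies close to the 0.40 cut-point relative
to its standard error at n = 500); the seasonal on-site ordering; and
the qualitative dose ordering — cohort-mean method 1 ≥ method 2 ≥
method 3 among grower-seasons with ≤ 8-hour workdays, and spring/summer
doses above fall/winter.  The method ordering is asserted on cohort
means, not per record: at exactly 8 h/day the method-2 indoor term
(which accrues over the whole month) exceeds method 1's margin for any
feasible days/month, so a per-record ordering cannot hold in general.

## Statistical summaries

`summarize_factor()` reports order statistics with optional zero
exclusion (box-plot summaries describe only engaged growers); the
quantile rule is linear interpolation between closest order statistics
(type 7), configurable because box-plot quartile conventions differ.
`compare_groups()`, `test_distribution()` and `correlate()` are thin
contracts over the standard Kruskal–Wallis, Shapiro–Wilk and
Pearson/Kendall routines — the contribution of this package is the
dose framework, not these tests — and their outputs carry `n` and
stratum labels so any printed summary is traceable.  No
multiple-testing correction is applied.

## Problem sizes

The shipped tests run the generator at n = 500 (and 2000 for the
threshold-assignment check), simulations at 100 000 draws for sampler
and oracle checks and 1000–10 000 draws for stability checks, and 1000
random fixtures for the cross-method reduction identity — sizes chosen
so each statistical assertion has comfortable power while the whole
suite stays quick on a single CPU.

## Known limitations

* Behaviour data (gloves, handwashing, positions) are captured and
  validated but never modify dose, mirroring the scope of the models.
* Dermal and inhalation pathways, and any toxicity or risk
  characterisation beyond dose, are out of scope.
* The annual aggregate (`annualize()`) is the sum of four seasonal
  ADDs — a cumulative index for comparison across growers and methods,
  not a dose rate — with the seasonal mean reported alongside.
* The shipped body-weight tables are synthetic placeholders.
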