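---
title: "Probability-based costing of NCD treatment services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based costing of NCD treatment services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probcost)
```

## The problem

Budgeting for non-communicable disease (NCD) treatment in a public
primary-care system normally needs per-condition headcounts and coverage
targets: total cost = unit cost × quantity, condition by condition. In
data-poor settings those quantities are simply not available. `probcost`
implements a hybrid work-around:

1. **Deterministic costing** prices each condition's treatment profile
   bottom-up (visits × components), which needs only price lists and
   treatment standards — both usually available.
2. **Probability-based costing (Symmetric Approximation, SA)** then drops the
   per-condition quantities entirely: the per-service cost is treated as a
   random variable, summarised by a normal "generic condition" distribution,
   and unit costs are read off that distribution at whatever assurance level
   the planner targets.

The product of a probability-indexed unit cost and the total projected
service volume is the budget estimate; comparing candidate budgets against
the same distribution yields overrun/underrun risks.

## Deterministic costing

Each condition comprises one or more visits; each visit consumes resources in
five classes: human resources, equipment, diagnostics, medical consumables,
medicine. The component formulas are the minimal readings of the verbal
costing rules:

* **Human resources** are shared across conditions, so salary is allocated
  pro rata by time: `annual_salary / annual_working_minutes × staff_minutes`.
  There is no hidden default for working minutes; tests and examples use
  105 600 min/yr (1 760 hours) and say so where they use it.
* **Equipment** is straight-line amortized and allocated per minute of use:
  `acquisition_cost / (lifespan_years × annual_use_minutes) × use_minutes`.
  (Per-use rather than per-minute allocation would be a one-line change in
  `equipment_cost()`; per-minute was chosen because treatment durations are
  what the input tables record.)
* **Diagnostics, consumables, medicines** are consumed per treatment and
  applied in full: `quantity × unit_price`.

Visit cost is the sum of component costs; condition unit cost the sum of
visit costs. Everything is additive and homogeneous in prices, which the test
suite checks against brute-force re-summation of the raw usage rows.
Overheads (administration, maintenance, electricity) are deliberately out of
scope. All money is carried at full floating precision; rounding happens only
at reporting boundaries.

```{r}
bases <- cost_bases(
  staff_cost_basis(annual_salary = 528000, annual_working_minutes = 105600),
  equipment_cost_basis(acquisition_cost = 10000, lifespan_years = 5,
                       annual_use_minutes = 40000)
)
human_resource_cost(20, bases$staff)   # 20 staff-minutes
equipment_cost(20, bases$equipment)    # 20 use-minutes
```

## Symmetric Approximation

For each component, a three-point estimate is derived from the per-condition
component totals of a population group:

* `low` / `high` — the minimum / maximum total over all conditions;
* `most_likely` — the mean total within the *top-ranked* condition category
  (categories are ranked by how frequently their conditions are treated;
  in the reference exercise cardiovascular ranked first for adults and
  "other conditions" first for children). The ranking is input data here —
  `generate_category_ranking()` either accepts it verbatim or draws a seeded
  permutation for synthetic studies.

Each three-point estimate is read as a **triangular distribution** (the
standard choice when only low/mode/high are known), with closed-form moments

$$\mu = \frac{l + m + h}{3}, \qquad
  \sigma^2 = \frac{l^2 + m^2 + h^2 - lm - lh - mh}{18}.$$

Uniform, normal and beta-PERT readings of the same three points are available
behind `component_summary(shape = )` — uniform `((l+h)/2, (h-l)^2/12)`,
normal `(m, ((h-l)/6)^2)`, beta-PERT `((l+4m+h)/6, ((h-l)/6)^2)` — but
triangular is the default and the only shape used in the reference results.

Component means and variances are **summed** (components are treated as
independent, so covariance terms are dropped — a modelling assumption, not an
estimate) and the total per-service cost is taken to be
$\mathcal{N}(\mu_\Sigma, \sigma_\Sigma^2)$. Unit costs at a target
probability are normal quantiles, computed with the high-accuracy inverse CDF
(`qnorm`, inversion error < 1e-9), never a printed table, and rounded half-up
to whole ZAR only at the reporting boundary (whole-ZAR unit costs are what
make the published total-cost products exact integers).

```{r}
adult <- component_summary(table1_components("adult"))
model <- aggregate_total(adult, group = "adult")
model
unit_cost_at_probability(model, c(0.50, 0.75, 0.90))
```

### The bundled reference fixture

`table1_components()` carries the published three-point table of the 2020
South African exercise. Two printed anomalies are carried as data, flagged,
and excluded from integrity checks rather than silently corrected:

* the adult diagnostics printed mean (275) contradicts the closed-form mean
  of its own three points (257.27) — and 257 is what makes the printed adult
  total mean work; it is almost certainly a digit transposition
  (`mean_anomalous = TRUE` in the fixture);
* small-magnitude printed variances are rounded to whole units, so fixture
  integrity is asserted to printed precision (0.01% relative or half a unit,
  whichever is looser).

Similarly, the provincial demand tables (`province_services()`) store the
rows and the printed national totals separately: the printed services columns
carry unit-level rounding (column sums differ from the printed totals by 1
adult / 2 child services), and one adult provincial row is internally
inconsistent with the others under any single projection-parameter setting.
The printed totals are what downstream products use.

## Budget overrun and underrun risk

A point of estimate (POE) — any candidate unit cost — is standardized against
the model, `z = (POE − µ)/σ`, and the overrun probability is `50% − tail(z)`
for a POE at or above the mean (`50% + tail(|z|)` below it), with underrun
its complement. Two dialects are first-class:

* **exact** (default): `tail(z) = Φ(|z|) − 0.5` at full precision;
* **table**: the classic printed-table workflow — z rounded to two decimals
  (rounding, not truncation; indistinguishable for the worked example),
  one-sided probability reported to four decimals.

The dialects agree within 0.6 percentage points for |z| ≤ 3 (the table's own
rounding bound, verified by sweep in the tests), and overrun + underrun is
exactly 100% in both before percent rounding.

```{r}
m <- normal_cost_model(3182, 951.630^2, "adult")
overrun_underrun(3824, m, dialect = "table")
```

## Service volumes

Where projection inputs exist, service counts come from

$$s = \frac{p\,(1+i)\,u}{(c + c_i)\,v}$$

(population grown one period, converted to visits via the utilisation rate,
adjusted for the planned coverage level, divided by average visits per
treatment episode). The published formula's grouping is typographically
ambiguous; this reading follows the accompanying prose order and is isolated
in `project_services()` so an alternative grouping is a one-line change. The
per-province projection parameters `(i, c, ci, v)` of the reference tables
were never published, so the package treats the printed services columns as
data and does not attempt to re-derive them.

## Reporting and multi-year costing

`cost_table()` crosses whole-ZAR unit costs at each target probability with
service counts into exact integer total-cost products, plus overrun/underrun
columns; `compare_budget()` signs the gap against a budget envelope. USD
figures are pass-through only: they appear only when the caller supplies an
exchange rate, because the reference report's own implied rates are mutually
inconsistent (≈17.96 within the cost table, ≈15.07 for the budget line).
`multi_year_adjust()` compounds prices by `(1+CPI)^years` (mean and sd scale
linearly, variance quadratically — the coefficient of variation is invariant)
and population by `(1+growth)^years`.

## Monte Carlo validation

`sample_total_cost()` draws each component directly from its triangular
distribution by closed-form inverse-transform sampling (no rejection, exact
seed reproducibility) and sums; `compare_sa_mc()` tabulates SA-vs-empirical
quantile gaps. Two findings worth knowing, both computed by the test suite:

* empirical moments converge to the closed forms at the Monte-Carlo rate
  (3-sigma bands at n from 1e3 to 1e6);
* the quality of the *quantile* agreement depends on how normal the
  five-component sum really is. For the adult fixture every reported quantile
  agrees within 2% at n = 1e6. For the child fixture the sum is dominated by
  one strongly right-skewed component, and the normal approximation carries a
  systematic gap at the median (around 7% relative, stable across seeds)
  while the 75% budgeting quantile still agrees within 2%. Planners using the
  child model at the median should expect the SA figure to sit above the
  simulated one.

## Synthetic data

`generate_condition_table()` emits condition profiles with known ground
truth: uniform price draws inside configured per-component ranges (bounded
support keeps range-recovery by `derive_component_ranges()` exact), uniform
category assignment unless per-category counts are fixed, seeded and
byte-reproducible. Defaults mirror the reference exercise's scale (58 adult /
40 child conditions, five categories, two population groups); price-range
defaults are order-of-magnitude ZAR figures a practitioner would recognise,
not calibrated to any dataset. What the generator does **not** emulate:
correlation between components within a visit, heavy-tailed price
distributions, missing or misdiagnosed records. Passing tests on synthetic
tables therefore demonstrate algorithmic correctness, not robustness to real
health-information-system data quality.

## Problem sizes and runtime

The test suite runs synthetic tables of 5–500 conditions and Monte Carlo
checks at up to 1e6 draws (vectorised sampling keeps the full suite at well
under a minute); the acceptance computation is a five-component closed-form
summary and runs in milliseconds.

## Limitations

* Independence across cost components is assumed when summing variances; no
  covariance estimation is attempted.
* The normal total-cost assumption is an approximation whose error grows with
  component skewness (see the child-group finding above).
* Indirect/overhead costs, geographic price variation beyond a CPI
  multiplier, and USD conversion as a validated output are out of scope.
* Single financial year per run; multi-year figures come from the explicit
  CPI/growth adjustment, not from within-episode discounting.
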