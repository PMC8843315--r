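# probcost

Hybrid deterministic + probability-based cost estimation for
non-communicable disease (NCD) treatment services in data-poor health
systems — for health economists, financial planners and health-service
researchers who must budget primary-care treatment without per-condition
headcount or coverage data.

## What it does

Classical costing needs `total cost = unit cost × quantity` per condition;
in most low- and middle-income settings the quantities do not exist.
`probcost` implements the work-around in two steps:

1. **Deterministic condition costing.** Each condition's treatment profile
   (visits × component usages) is priced bottom-up over five components —
   human resources (salary allocated pro rata by staff-minutes), equipment
   (straight-line amortization per use-minute), diagnostics, medical
   consumables and medicine (consumed in full, quantity × price).

2. **Symmetric Approximation (SA).** Per component, a three-point estimate
   (low, most likely, high) is derived from the per-condition totals and read
   as a triangular distribution with

   μ = (l + m + h)/3,  σ² = (l² + m² + h² − lm − lh − mh)/18.

   Component means and variances are summed (independence assumed) and the
   total per-service cost is treated as N(μΣ, σΣ²) — a "generic condition"
   distribution. Unit costs at any assurance level are its quantiles; budget
   overrun risk for a point of estimate (POE) follows from
   z = (POE − μ)/σ. Multiplying a probability-indexed unit cost by the
   projected service volume `s = p(1+i)·u / ((c+ci)·v)` gives the budget
   estimate; a Monte Carlo oracle (direct triangular sampling) validates the
   closed-form approximation.

The package ships the published 2020 South African case-study tables as
read-only fixtures, a seeded synthetic-data generator for ground-truth
testing, a config-driven pipeline with reproducible manifests, and a thin
CLI (`inst/exec/probcost`).

## Worked example

```r
library(probcost)

# Normal total-cost model from the bundled three-point component table
adult <- component_summary(table1_components("adult"))
model <- aggregate_total(adult, group = "adult")
model
#> <normal cost model: adult>
#>   mean 3182.31 ZAR | sd 951.646 ZAR | variance 905629.2 | CV 29.90%

unit_cost_at_probability(model, c(0.50, 0.75, 0.90))
#> [1] 3182 3824 4402

# Budget risk of funding at the 75% unit cost
overrun_underrun(3824, normal_cost_model(3182, 951.630^2), dialect = "table")
#> <budget risk, table dialect> POE 3,824 | z = 0.674632
#>   overrun 25% | underrun 75%

# Full pipeline on the case-study fixtures
res <- run_pipeline(fixture_config(), output_dir = tempfile("run"))
res$report[res$report$probability == 0.50, c("population_group", "unit_cost",
                                             "services", "total_cost")]
#> # A tibble: 2 × 4
#>   population_group unit_cost services  total_cost
#>   <chr>                <dbl>    <dbl>       <dbl>
#> 1 adult                 3182 11588626 36875007932
#> 2 child                 1146  8023449  9194872554
res$comparison
#> <budget comparison>
#>   estimate 46,069,880,486 ZAR | budget 19,581,032,000 ZAR
#>   gap 26,488,848,486 ZAR (underfunded)
```

Reading: at the 50% assurance level one adult treatment service costs
ZAR 3 182 and the 11.6M projected adult services plus 8.0M child services
cost ZAR 46.07bn — against a ZAR 19.58bn envelope, a 26.49bn shortfall.

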