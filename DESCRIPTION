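Package: probcost
Title: Hybrid Deterministic and Probability-Based Costing of Health Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cost of delivering non-communicable disease (NCD)
    treatment services in data-poor settings by combining deterministic
    bottom-up ingredient costing with probability-based cost estimation
    (Symmetric Approximation). Condition treatment profiles are costed per
    visit and cost component; three-point (low, most likely, high) estimates
    per component are summarised with triangular-distribution moments, summed
    into a normal total-cost model, and inverted to unit costs at target
    probabilities. Includes budget overrun/underrun risk via z-scores,
    service-volume projection from population, utilisation and coverage,
    total-cost and budget-gap reporting with multi-year CPI/growth adjustment,
    a seeded synthetic-data generator, and a Monte Carlo oracle that validates
    the closed-form approximation by direct triangular sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
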