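test_that("component ranges take global min/max and top-category mean", {
  costs <- tibble::tibble(
    condition_id = sprintf("C%d", 1:4),
    category = c("other", "cardiovascular", "cardiovascular", "cancer"),
    population_group = "adult",
    component_type = "medicine",
    total = c(10, 20, 30, 40)
  )
  r <- derive_component_ranges(costs, c("cardiovascular", "other", "cancer"))
  expect_equal(r$low, 10)
  expect_equal(r$most_likely, 25)   # mean of the cardiovascular totals {20, 30}
  expect_equal(r$high, 40)

  # a single condition collapses the estimate to a point
  one <- costs[2, ]
  r1 <- derive_component_ranges(one, "cardiovascular")
  expect_equal(c(r1$low, r1$most_likely, r1$high), c(20, 20, 20))

  # failure modes: uncovered category, empty top category
  expect_error(derive_component_ranges(costs, c("cardiovascular", "other")),
               class = "probcost_ranking_error")
  expect_error(derive_component_ranges(costs[1, ], c("cancer", "other")),
               class = "probcost_ranking_error")
})

test_that("top-ranked category drives the mode for every component", {
  cfg <- generator_config(n_conditions = 30, seed = 11)
  conditions <- generate_condition_table(cfg)
  costs <- condition_cost_table(conditions, toy_bases())
  ranking <- generate_category_ranking(unique(costs$category), seed = 2)
  r <- derive_component_ranges(costs, ranking)
  top <- ranking[1]
  for (i in seq_len(nrow(r))) {
    comp <- costs[costs$component_type == r$component_type[i], ]
    expect_equal(r$low[i], min(comp$total))
    expect_equal(r$high[i], max(comp$total))
    expect_equal(r$most_likely[i],
                 mean(comp$total[comp$category == top]))
  }
})

test_that("aggregation sums moments into a coherent normal model", {
  adult <- component_summary(table1_components("adult"))
  model <- aggregate_total(adult, group = "adult")
  expect_equal(model$mean, sum(adult$mean))
  expect_equal(model$variance, sum(adult$variance))
  expect_equal(model$sd, sqrt(model$variance))
  expect_equal(model$cv, model$sd / model$mean)

  # published totals row: mean 3 182, variance 905 600, sd 951.630, CV 29.90%
  expect_equal(model$mean, 3182, tolerance = 5e-4)
  expect_equal(model$variance, 905600, tolerance = 5e-4)
  expect_equal(model$sd, 951.630, tolerance = 5e-4)
  expect_equal(100 * model$cv, 29.90, tolerance = 0.02 / 29.90)

  child <- aggregate_total(component_summary(table1_components("child")),
                           group = "child")
  expect_equal(child$mean, 1146, tolerance = 5e-4)
  expect_equal(child$variance, 279446, tolerance = 5e-4)

  # identity on a single component; permutation invariance
  single <- adult[3, ]
  m1 <- aggregate_total(single)
  expect_equal(c(m1$mean, m1$variance), c(single$mean, single$variance))
  perm <- aggregate_total(adult[c(4, 1, 5, 2, 3), ])
  expect_equal(perm$mean, model$mean)
  expect_equal(perm$variance, model$variance)
  expect_error(aggregate_total(adult[0, ]), class = "probcost_input_error")
})

test_that("unit costs at probability reproduce the published quantiles", {
  m <- fixture_models()
  expect_equal(unit_cost_at_probability(m$adult, 0.50), 3182)
  expect_equal(unit_cost_at_probability(m$adult, 0.75), 3824)
  expect_equal(unit_cost_at_probability(m$adult, 0.90), 4402)
  expect_equal(unit_cost_at_probability(m$child, 0.75), 1503)
  # the median of a normal is its mean
  expect_equal(unit_cost_at_probability(m$adult, 0.50, round = FALSE),
               m$adult$mean)
  expect_error(unit_cost_at_probability(m$adult, 1),
               class = "probcost_input_error")
})

test_that("quantiles are monotone and invert the CDF to 1e-9", {
  m <- fixture_models()$adult
  p <- seq(0.01, 0.99, by = 0.01)
  q <- unit_cost_at_probability(m, p, round = FALSE)
  expect_true(all(diff(q) > 0))
  expect_equal(stats::pnorm(q, m$mean, m$sd), p, tolerance = 1e-9)
})
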