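test_that("human-resource cost allocates salary pro rata by minutes", {
  basis <- staff_cost_basis(528000, 105600)
  expect_equal(human_resource_cost(20, basis), 100)    # 528000/105600 * 20
  expect_equal(human_resource_cost(0, basis), 0)
  expect_equal(human_resource_cost(40, basis), 2 * human_resource_cost(20, basis))
  expect_error(staff_cost_basis(528000, 0), class = "probcost_input_error")
})

test_that("equipment cost amortizes acquisition over lifespan use-minutes", {
  basis <- equipment_cost_basis(10000, 5, 40000)
  expect_equal(equipment_cost(20, basis), 1)           # 10000/(5*40000) * 20
  expect_equal(equipment_cost(0, basis), 0)
  expect_equal(equipment_cost(20, equipment_cost_basis(0, 5, 40000)), 0)
  expect_error(equipment_cost_basis(10000, 0, 40000),
               class = "probcost_input_error")
})

test_that("consumed components are applied in full", {
  expect_equal(consumed_cost(2, 15.25), 30.50)
  expect_equal(consumed_cost(0, 99), 0)
  expect_equal(consumed_cost(1, 94.30, "diagnostics"), 94.30)
  expect_error(consumed_cost(1, 10, "equipment"),
               class = "probcost_component_error")
})

test_that("visit cost sums the five component subtotals", {
  vc <- visit_cost(toy_visit(), toy_bases())
  expect_equal(vc$total, 193.50)
  expect_equal(sort(names(vc$breakdown)), sort(component_types()))
  expect_equal(unname(vc$breakdown[c("human_resources", "equipment",
                                     "medical_consumables", "medicine",
                                     "diagnostics")]),
               c(100, 1, 12.50, 30, 50))
  expect_equal(sum(vc$breakdown), vc$total)

  # empty visit costs nothing; permutation leaves the total unchanged
  empty <- toy_visit()[0, ]
  expect_equal(visit_cost(empty, toy_bases())$total, 0)
  shuffled <- toy_visit()[c(4, 1, 5, 3, 2), ]
  expect_equal(visit_cost(shuffled, toy_bases())$total, 193.50)

  bad <- toy_visit(); bad$component_type[1] <- "catering"
  expect_error(visit_cost(bad, toy_bases()),
               class = "probcost_component_error")
})

test_that("condition unit cost is additive over visits and components", {
  cond <- toy_condition(n_visits = 3)
  cc <- condition_unit_cost(cond, toy_bases())
  expect_equal(cc$total, 3 * 193.50)
  expect_equal(unname(cc$visit_costs), rep(193.50, 3))
  expect_equal(sum(cc$breakdown), cc$total)
  expect_error(condition_unit_cost(cond[0, ], toy_bases()),
               class = "probcost_input_error")
})

test_that("costing is homogeneous of degree one in prices", {
  cond <- toy_condition(n_visits = 2)
  base <- condition_unit_cost(cond, toy_bases())
  scaled <- cond; scaled$unit_price <- scaled$unit_price * 3.5
  # scale the basis prices consistently (row prices override salary/acquisition)
  cc <- condition_unit_cost(scaled, toy_bases())
  expect_equal(cc$total, 3.5 * base$total)
  expect_equal(unname(cc$breakdown), 3.5 * unname(base$breakdown))
})

test_that("condition cost table matches a brute-force re-sum over usages", {
  cfg <- generator_config(n_conditions = 12, seed = 404,
                          visits_range = c(1L, 4L), usages_range = c(0L, 2L))
  conditions <- generate_condition_table(cfg)
  got <- condition_cost_table(conditions, toy_bases())
  oracle <- brute_force_component_totals(conditions, toy_bases())
  got_nonzero <- got[got$total > 0, c("condition_id", "component_type", "total")]
  got_nonzero <- got_nonzero[order(got_nonzero$condition_id,
                                   got_nonzero$component_type), ]
  expect_equal(got_nonzero$total, oracle$total, tolerance = 1e-12)
  # per-component totals sum to the condition unit cost
  sums <- tapply(got$total, got$condition_id, sum)
  units <- tapply(got$unit_cost, got$condition_id, function(x) x[1])
  expect_equal(unname(sums), unname(units[names(sums)]))
  expect_true(all(got$total >= 0))
})
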