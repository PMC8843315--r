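# Shared toy fixtures for the costing tests. The staff basis corresponds to
# 1,760 working hours/year (105,600 minutes); the equipment basis to a
# 10,000 ZAR instrument amortized over 5 years at 40,000 use-minutes/year.

toy_bases <- function() {
  cost_bases(
    staff_cost_basis(annual_salary = 528000, annual_working_minutes = 105600),
    equipment_cost_basis(acquisition_cost = 10000, lifespan_years = 5,
                         annual_use_minutes = 40000)
  )
}

# One visit using all five components with easily hand-checked costs:
# HR 100 (20 min at 5 ZAR/min), equipment 1 (20 min at 0.05 ZAR/min),
# consumables 12.50, medicine 30, diagnostics 50. Total 193.50.
toy_visit <- function(visit_index = 1L) {
  tibble::tibble(
    visit_index = visit_index,
    component_type = c("human_resources", "equipment", "medical_consumables",
                       "medicine", "diagnostics"),
    quantity = c(1, 1, 1, 2, 1),
    unit_price = c(528000, 10000, 12.50, 15, 50),
    duration_min = c(20, 20, 0, 0, 0)
  )
}

toy_condition <- function(n_visits = 1L) {
  rows <- do.call(rbind, lapply(seq_len(n_visits), toy_visit))
  tibble::tibble(condition_id = "C001", category = "cardiovascular",
                 population_group = "adult", rows)
}

# Full-precision total-cost models recomputed from the three-point fixture.
fixture_models <- function() sa_models_from_table1()

# Independent brute-force costing of a condition table: applies the component
# formulas row by row, bypassing visit_cost()/condition_unit_cost().
brute_force_component_totals <- function(conditions, bases) {
  per_row <- mapply(function(ct, q, price, mins) {
    switch(ct,
      human_resources = price / bases$staff$annual_working_minutes * mins,
      equipment = price / (bases$equipment$lifespan_years *
                             bases$equipment$annual_use_minutes) * mins,
      q * price)
  }, conditions$component_type, conditions$quantity, conditions$unit_price,
     conditions$duration_min)
  out <- stats::aggregate(
    list(total = per_row),
    by = list(condition_id = conditions$condition_id,
              component_type = conditions$component_type),
    FUN = sum)
  out[order(out$condition_id, out$component_type), ]
}
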