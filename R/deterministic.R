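# Deterministic (bottom-up, ingredients-based) costing of one condition:
# cost each component of each prescribed visit, then aggregate.
#
# Human resources are allocated pro rata from annual salary by staff-minutes;
# equipment is straight-line amortized over its lifespan pro rata by minutes
# of use; diagnostics, medical consumables and medicines are consumed in full
# per treatment (quantity x unit price).

#' Staff cost basis
#'
#' Converts an annual salary into a per-minute rate.
#'
#' @param annual_salary annual salary (ZAR/year).
#' @param annual_working_minutes productive minutes worked per year; e.g.
#'   1 760 hours/year = 105 600 minutes.
#' @return an object of class `staff_cost_basis`.
#' @export
staff_cost_basis <- function(annual_salary, annual_working_minutes) {
  check_number(annual_salary, "annual_salary", min = 0)
  check_number(annual_working_minutes, "annual_working_minutes",
               min = 0, strict_min = TRUE)
  structure(list(annual_salary = annual_salary,
                 annual_working_minutes = annual_working_minutes),
            class = "staff_cost_basis")
}

#' Equipment cost basis
#'
#' Straight-line amortization of an acquisition cost over the equipment's
#' lifespan, allocated per minute of use.
#'
#' @param acquisition_cost purchase cost (ZAR).
#' @param lifespan_years useful life (years).
#' @param annual_use_minutes minutes of use per year.
#' @return an object of class `equipment_cost_basis`.
#' @export
equipment_cost_basis <- function(acquisition_cost, lifespan_years,
                                 annual_use_minutes) {
  check_number(acquisition_cost, "acquisition_cost", min = 0)
  check_number(lifespan_years, "lifespan_years", min = 0, strict_min = TRUE)
  check_number(annual_use_minutes, "annual_use_minutes",
               min = 0, strict_min = TRUE)
  structure(list(acquisition_cost = acquisition_cost,
                 lifespan_years = lifespan_years,
                 annual_use_minutes = annual_use_minutes),
            class = "equipment_cost_basis")
}

#' Default costing bases
#'
#' Convenience constructor bundling a staff basis and an equipment basis, the
#' two allocation keys deterministic costing needs beyond the usage table
#' itself. There are no hidden defaults: the toy values used in tests and
#' examples (105 600 working minutes/year, i.e. 1 760 hours) are stated where
#' they are used.
#'
#' @param staff a [staff_cost_basis()].
#' @param equipment an [equipment_cost_basis()].
#' @return a list with elements `staff` and `equipment`.
#' @export
cost_bases <- function(staff, equipment) {
  stopifnot(inherits(staff, "staff_cost_basis"),
            inherits(equipment, "equipment_cost_basis"))
  list(staff = staff, equipment = equipment)
}

#' Human-resource cost of a usage
#'
#' Allocates annual salary pro rata by staff time:
#' `annual_salary / annual_working_minutes * staff_minutes`. Linear in
#' minutes.
#'
#' @param staff_minutes staff time spent on the visit (minutes).
#' @param basis a [staff_cost_basis()].
#' @return cost in ZAR.
#' @examples
#' human_resource_cost(20, staff_cost_basis(528000, 105600))  # 100 ZAR
#' @export
human_resource_cost <- function(staff_minutes, basis) {
  check_number(staff_minutes, "staff_minutes", min = 0)
  stopifnot(inherits(basis, "staff_cost_basis"))
  basis$annual_salary / basis$annual_working_minutes * staff_minutes
}

#' Equipment cost of a usage
#'
#' `acquisition_cost / (lifespan_years * annual_use_minutes) * use_minutes`:
#' the per-minute amortized cost times the minutes of use in the visit.
#'
#' @param use_minutes minutes the equipment is used in the visit.
#' @param basis an [equipment_cost_basis()].
#' @return cost in ZAR.
#' @examples
#' equipment_cost(20, equipment_cost_basis(10000, 5, 40000))  # 1 ZAR
#' @export
equipment_cost <- function(use_minutes, basis) {
  check_number(use_minutes, "use_minutes", min = 0)
  stopifnot(inherits(basis, "equipment_cost_basis"))
  basis$acquisition_cost /
    (basis$lifespan_years * basis$annual_use_minutes) * use_minutes
}

#' Cost of a fully consumed component
#'
#' Diagnostics, medical consumables and medicines are consumed per treatment
#' and applied in full: `quantity * unit_price`.
#'
#' @param quantity units consumed.
#' @param unit_price price per unit (ZAR).
#' @param component_type one of `"diagnostics"`, `"medical_consumables"`,
#'   `"medicine"`; checked so amortized components cannot be costed this way
#'   by mistake.
#' @return cost in ZAR.
#' @export
consumed_cost <- function(quantity, unit_price,
                          component_type = "medical_consumables") {
  if (!component_type %in% CONSUMED_TYPES) {
    abort_probcost(
      sprintf("component type '%s' is not consumed per treatment", component_type),
      "probcost_component_error"
    )
  }
  check_number(quantity, "quantity", min = 0)
  check_number(unit_price, "unit_price", min = 0)
  quantity * unit_price
}

# Cost one usage row (component_type, quantity, unit_price, duration_min).
usage_cost <- function(component_type, quantity, unit_price, duration_min,
                       bases) {
  switch(component_type,
    human_resources = human_resource_cost(duration_min, bases$staff),
    equipment = equipment_cost(duration_min, bases$equipment),
    diagnostics = ,
    medical_consumables = ,
    medicine = consumed_cost(quantity, unit_price, component_type),
    abort_probcost(sprintf("unknown component type '%s'", component_type),
                   "probcost_component_error")
  )
}

#' Cost of one visit
#'
#' Sums the component costs of all usages in a visit and reports a
#' per-component breakdown. Component types without usages contribute zero.
#'
#' @param usages a data frame with columns `component_type`, `quantity`,
#'   `unit_price`, `duration_min` (one row per resource used in the visit).
#'   For human resources `unit_price` is the annual salary of the staff cadre
#'   and `duration_min` the staff-minutes; for equipment `unit_price` is the
#'   acquisition cost and `duration_min` the minutes of use; for consumed
#'   components `quantity` and `unit_price` apply directly.
#' @param bases a [cost_bases()] list. When a usage row carries its own salary
#'   or acquisition cost, the bases supply the remaining allocation keys
#'   (working minutes; lifespan and annual use); rows are costed with
#'   per-row prices overriding the basis price when `use_row_prices = TRUE`.
#' @param use_row_prices if `TRUE` (default), human-resource and equipment
#'   rows use the row's `unit_price` as salary/acquisition cost together with
#'   the basis allocation keys; if `FALSE` the basis prices are used for all
#'   rows.
#' @return a list with elements `total` (ZAR) and `breakdown` (named numeric
#'   over the five component types).
#' @export
visit_cost <- function(usages, bases, use_row_prices = TRUE) {
  breakdown <- stats::setNames(numeric(length(COMPONENT_TYPES)), COMPONENT_TYPES)
  if (nrow(usages) > 0L) {
    bad <- setdiff(unique(usages$component_type), COMPONENT_TYPES)
    if (length(bad)) {
      abort_probcost(sprintf("unknown component type(s): %s",
                             paste(bad, collapse = ", ")),
                     "probcost_component_error")
    }
    costs <- vapply(seq_len(nrow(usages)), function(i) {
      row <- usages[i, ]
      b <- bases
      if (use_row_prices) {
        if (row$component_type == "human_resources") {
          b$staff <- staff_cost_basis(row$unit_price,
                                      bases$staff$annual_working_minutes)
        } else if (row$component_type == "equipment") {
          b$equipment <- equipment_cost_basis(
            row$unit_price, bases$equipment$lifespan_years,
            bases$equipment$annual_use_minutes)
        }
      }
      usage_cost(row$component_type, row$quantity, row$unit_price,
                 row$duration_min, b)
    }, numeric(1))
    sums <- tapply(costs, factor(usages$component_type, COMPONENT_TYPES), sum)
    sums[is.na(sums)] <- 0
    breakdown[] <- sums
  }
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Condition unit cost
#'
#' The deterministic total cost of treating one condition: the sum of its
#' visit costs, with per-component totals across all visits.
#'
#' @param condition a data frame holding all usage rows of one condition, with
#'   columns `visit_index`, `component_type`, `quantity`, `unit_price`,
#'   `duration_min`.
#' @inheritParams visit_cost
#' @return a list with elements `total` (ZAR), `breakdown` (named numeric over
#'   component types) and `visit_costs` (numeric, one per visit).
#' @export
condition_unit_cost <- function(condition, bases, use_row_prices = TRUE) {
  if (nrow(condition) == 0L) {
    abort_probcost("a condition must have at least one visit",
                   "probcost_input_error")
  }
  visits <- split(condition, condition$visit_index)
  per_visit <- lapply(visits, visit_cost, bases = bases,
                      use_row_prices = use_row_prices)
  breakdown <- Reduce(`+`, lapply(per_visit, `[[`, "breakdown"))
  list(
    total = sum(breakdown),
    breakdown = breakdown,
    visit_costs = vapply(per_visit, `[[`, numeric(1), "total")
  )
}

#' Per-condition, per-component cost totals
#'
#' Costs every condition in a long-format condition table and returns the
#' per-component totals — the input ranked by the probability-based step to
#' derive three-point estimates.
#'
#' @param conditions a condition table (see [generate_condition_table()]) with
#'   columns `condition_id`, `category`, `population_group`, `visit_index`,
#'   `component_type`, `quantity`, `unit_price`, `duration_min`.
#' @inheritParams visit_cost
#' @return a tibble with one row per condition and component type:
#'   `condition_id`, `category`, `population_group`, `component_type`,
#'   `total` (ZAR); plus `unit_cost` repeated per condition.
#' @export
condition_cost_table <- function(conditions, bases, use_row_prices = TRUE) {
  parts <- lapply(split(conditions, conditions$condition_id), function(df) {
    cc <- condition_unit_cost(df, bases, use_row_prices)
    tibble::tibble(
      condition_id = df$condition_id[1L],
      category = df$category[1L],
      population_group = df$population_group[1L],
      component_type = names(cc$breakdown),
      total = unname(cc$breakdown),
      unit_cost = cc$total
    )
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
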