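# Reporting: unit costs at target probabilities x projected services =
# total-cost estimates; comparison against a budget envelope; multi-year
# CPI/population-growth adjustment. All ZAR totals are exact integer products
# of whole-ZAR unit costs and service counts.

#' Total cost from unit cost and services
#'
#' Exact product `unit_cost * services`; whole inputs give an exact integer
#' total (no floating drift for realistic budget magnitudes).
#'
#' @param unit_cost unit cost (ZAR), normally whole.
#' @param services number of services.
#' @return total cost in ZAR.
#' @examples
#' total_cost(3182, 11588626)  # 36,875,007,932
#' @export
total_cost <- function(unit_cost, services) {
  check_number(unit_cost, "unit_cost", min = 0)
  check_number(services, "services", min = 0)
  unit_cost * services
}

#' Combined total-cost estimate across population groups
#'
#' At one target probability, rounds each group's unit cost to whole ZAR,
#' multiplies by that group's services, and sums across groups.
#'
#' @param models named list of [normal_cost_model()]s, one per population
#'   group.
#' @param services named numeric of service counts; names must cover the
#'   model names.
#' @param probability single target probability in (0, 1).
#' @return combined total cost (ZAR).
#' @examples
#' models <- sa_models_from_table1()
#' combined_estimate(models,
#'                   c(adult = 11588626, child = 8023449), 0.50)
#' @export
combined_estimate <- function(models, services, probability) {
  groups <- names(models)
  missing <- setdiff(groups, names(services))
  if (length(missing)) {
    abort_probcost(sprintf("no service count for group(s): %s",
                           paste(missing, collapse = ", ")),
                   "probcost_input_error")
  }
  sum(vapply(groups, function(g) {
    total_cost(unit_cost_at_probability(models[[g]], probability, round = TRUE),
               services[[g]])
  }, numeric(1)))
}

#' Total-cost report at target probabilities
#'
#' Builds the published-style report: one row per probability and population
#' group with the whole-ZAR unit cost, overrun/underrun percentages, service
#' count, and the exact total-cost product. USD columns are emitted only when
#' an exchange rate is supplied (pass-through; never asserted).
#'
#' @inheritParams combined_estimate
#' @param probabilities probabilities to report (default 0.50, 0.75, 0.90).
#' @param exchange_rate optional ZAR-per-USD rate; adds `unit_cost_usd` and
#'   `total_cost_usd` columns.
#' @param dialect risk dialect for the overrun column, see
#'   [overrun_underrun()].
#' @return a tibble with columns `probability`, `population_group`,
#'   `unit_cost`, `overrun_pct`, `underrun_pct`, `services`, `total_cost`
#'   (plus USD columns when a rate is given).
#' @export
cost_table <- function(models, services,
                       probabilities = c(0.50, 0.75, 0.90),
                       exchange_rate = NULL,
                       dialect = "exact") {
  if (length(probabilities) == 0L) {
    abort_probcost("at least one probability is required",
                   "probcost_input_error")
  }
  if (any(probabilities <= 0 | probabilities >= 1)) {
    abort_probcost("probabilities must lie strictly in (0, 1)",
                   "probcost_input_error")
  }
  rows <- list()
  for (p in probabilities) {
    for (g in names(models)) {
      uc <- unit_cost_at_probability(models[[g]], p, round = TRUE)
      risk <- overrun_underrun(uc, models[[g]], dialect = dialect)
      svc <- services[[g]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        probability = p,
        population_group = g,
        unit_cost = uc,
        overrun_pct = round_half_up(100 * risk$overrun),
        underrun_pct = round_half_up(100 * risk$underrun),
        services = svc,
        total_cost = total_cost(uc, svc)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(exchange_rate)) {
    check_number(exchange_rate, "exchange_rate", min = 0, strict_min = TRUE)
    out$unit_cost_usd <- out$unit_cost / exchange_rate
    out$total_cost_usd <- out$total_cost / exchange_rate
  }
  out
}

#' Compare an estimate against a budget envelope
#'
#' @param estimate estimated total cost (ZAR).
#' @param budget budgeted amount (ZAR).
#' @return an object of class `budget_comparison`: list with `budget`,
#'   `estimate`, `gap` (`estimate - budget`) and `direction` (`"underfunded"`
#'   when the estimate exceeds the budget, `"overfunded"` when below,
#'   `"balanced"` when equal).
#' @examples
#' compare_budget(46069880486, za_clinic_budget_2020())
#' @export
compare_budget <- function(estimate, budget) {
  check_number(estimate, "estimate", min = 0)
  check_number(budget, "budget", min = 0)
  gap <- estimate - budget
  structure(
    list(budget = budget, estimate = estimate, gap = gap,
         direction = if (gap > 0) "underfunded"
                     else if (gap < 0) "overfunded" else "balanced"),
    class = "budget_comparison"
  )
}

#' @export
print.budget_comparison <- function(x, ...) {
  cat("<budget comparison>\n")
  cat(sprintf("  estimate %s ZAR | budget %s ZAR\n",
              format_zar(x$estimate), format_zar(x$budget)))
  cat(sprintf("  gap %s ZAR (%s)\n", format_zar(x$gap), x$direction))
  invisible(x)
}

#' Multi-year CPI and population-growth adjustment
#'
#' Projects the costing inputs `years` ahead: prices (and hence the model's
#' mean and sd) are inflated by `(1 + cpi)^years`, the variance by its square
#' — leaving the coefficient of variation unchanged — and population by
#' `(1 + growth)^years`.
#'
#' @param model a [normal_cost_model()].
#' @param cpi annual consumer-price-inflation rate (fraction; > -1).
#' @param years number of years ahead (>= 0).
#' @param population optional population count to grow alongside.
#' @param growth annual population growth rate (fraction; > -1).
#' @return a list with `model` (adjusted [normal_cost_model()]) and
#'   `population` (adjusted, or `NULL` if not supplied).
#' @examples
#' m <- normal_cost_model(100, 25)
#' multi_year_adjust(m, cpi = 0.05, years = 2)$model$mean  # 110.25
#' @export
multi_year_adjust <- function(model, cpi, years, population = NULL,
                              growth = 0) {
  stopifnot(inherits(model, "normal_cost_model"))
  check_number(years, "years", min = 0)
  if (cpi <= -1 || growth <= -1) {
    abort_probcost("cpi and growth must be greater than -1",
                   "probcost_input_error")
  }
  f <- (1 + cpi)^years
  adjusted <- normal_cost_model(model$mean * f, model$variance * f^2,
                                model$group)
  list(
    model = adjusted,
    population = if (is.null(population)) NULL
                 else population * (1 + growth)^years
  )
}

#' Total-cost models recomputed from the published three-point table
#'
#' Convenience accessor: triangular component summaries of
#' [table1_components()] aggregated into adult and child
#' [normal_cost_model()]s at full precision (no intermediate rounding).
#'
#' @return named list with elements `adult` and `child`.
#' @export
sa_models_from_table1 <- function() {
  list(
    adult = aggregate_total(component_summary(table1_components("adult")),
                            group = "adult"),
    child = aggregate_total(component_summary(table1_components("child")),
                            group = "child")
  )
}
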