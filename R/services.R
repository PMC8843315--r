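# Service-volume projection: from population, growth, utilisation and
# coverage to the number of treatment services (episodes), plus province-level
# demand-table management.

#' Project the number of treatment services
#'
#' `s = p * (1 + i) * u * (1 / (c + ci)) / v`: the population is grown by one
#' period, converted to expected visits via the utilisation rate, adjusted for
#' the planned coverage level, and divided by the average number of visits per
#' treatment episode of the most likely condition category.
#'
#' @param population persons in the group/geography (`p`).
#' @param growth_rate population growth rate per period (`i`, fraction).
#' @param utilisation visits per person per period (`u`).
#' @param coverage coverage level: headcount / headcount target (`c`).
#' @param coverage_increase planned coverage increase rate (`ci`, fraction);
#'   `coverage + coverage_increase` must be positive.
#' @param visits_per_episode average visits per treatment episode for the most
#'   likely condition category (`v`, positive).
#' @param round round half-up to whole services (reporting convention).
#' @return projected number of services.
#' @examples
#' project_services(100000, 0.02, 2.5, 0.8, 0.05, 4)  # 75,000
#' @export
project_services <- function(population, growth_rate = 0, utilisation = 1,
                             coverage = 1, coverage_increase = 0,
                             visits_per_episode = 1, round = TRUE) {
  check_number(population, "population", min = 0)
  check_number(utilisation, "utilisation", min = 0)
  check_number(visits_per_episode, "visits_per_episode",
               min = 0, strict_min = TRUE)
  if (coverage + coverage_increase <= 0) {
    abort_probcost("coverage + coverage_increase must be positive",
                   "probcost_input_error")
  }
  s <- population * (1 + growth_rate) * utilisation /
    (coverage + coverage_increase) / visits_per_episode
  if (round) round_half_up(s) else s
}

#' Coverage from headcount and target
#'
#' `coverage = headcount / headcount_target`: the proportion of the visit
#' target actually served in the period.
#'
#' @param headcount visits recorded in the period.
#' @param headcount_target visit target for the period (positive).
#' @return coverage as a fraction.
#' @export
coverage <- function(headcount, headcount_target) {
  check_number(headcount, "headcount", min = 0)
  check_number(headcount_target, "headcount_target", min = 0,
               strict_min = TRUE)
  headcount / headcount_target
}

#' Aggregate province demand records to national totals
#'
#' Component-wise sums of population, headcount and services over a province
#' table; province labels must be unique.
#'
#' @param records a tibble with columns `province`, `population`,
#'   `phc_headcount`, `services` (e.g. from [province_services()]).
#' @return a one-row tibble with the national `population`, `phc_headcount`
#'   and `services` totals.
#' @examples
#' aggregate_provinces(province_services("adult"))
#' @export
aggregate_provinces <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort_probcost("at least one province record is required",
                   "probcost_input_error")
  }
  if (anyDuplicated(records$province)) {
    abort_probcost("duplicate province labels", "probcost_input_error")
  }
  tibble::tibble(
    population = sum(records$population),
    phc_headcount = sum(records$phc_headcount),
    services = sum(records$services)
  )
}
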