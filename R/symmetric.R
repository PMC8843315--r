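# Symmetric Approximation: the closed-form alternative to Monte Carlo.
# Three-point estimates per cost component are summarised by triangular
# moments; component means and variances are summed (independence assumed)
# into a normal model of the total per-service cost, whose quantiles give
# unit costs at target probabilities.

#' Derive three-point component estimates from condition costs
#'
#' For each cost component within a population group: `low` is the minimum
#' per-condition component total, `high` the maximum, and `most_likely` the
#' arithmetic mean of the component's totals within the top-ranked condition
#' category (the category health professionals rank as most frequently
#' treated). The mode is clamped into `[low, high]`.
#'
#' @param condition_costs a tibble of per-condition per-component totals as
#'   returned by [condition_cost_table()] (columns `condition_id`, `category`,
#'   `component_type`, `total`; rows for one population group).
#' @param ranking ordered character vector of category labels, most frequently
#'   treated first; must cover all categories present.
#' @return a tibble with columns `component_type`, `low`, `most_likely`,
#'   `high`.
#' @export
derive_component_ranges <- function(condition_costs, ranking) {
  if (nrow(condition_costs) == 0L) {
    abort_probcost("at least one condition is required", "probcost_input_error")
  }
  present <- unique(condition_costs$category)
  missing <- setdiff(present, ranking)
  if (length(missing)) {
    abort_probcost(sprintf("ranking does not cover categories: %s",
                           paste(missing, collapse = ", ")),
                   "probcost_ranking_error")
  }
  top <- ranking[1L]
  top_rows <- condition_costs[condition_costs$category == top, ]
  if (nrow(top_rows) == 0L) {
    abort_probcost(
      sprintf("top-ranked category '%s' has no conditions in this group", top),
      "probcost_ranking_error"
    )
  }
  comps <- unique(condition_costs$component_type)
  rows <- lapply(comps, function(ct) {
    totals <- condition_costs$total[condition_costs$component_type == ct]
    mode_pool <- top_rows$total[top_rows$component_type == ct]
    lo <- min(totals); hi <- max(totals)
    ml <- mean(mode_pool)
    tibble::tibble(component_type = ct, low = lo,
                   most_likely = min(max(ml, lo), hi), high = hi)
  })
  do.call(rbind, rows)
}

#' Normal total-cost model
#'
#' The "generic condition" distribution of a population group: total
#' per-service cost treated as Normal(mean, sd).
#'
#' @param mean total-cost mean (ZAR).
#' @param variance total-cost variance (ZAR^2).
#' @param group population group label (e.g. `"adult"`).
#' @return an object of class `normal_cost_model` with fields `group`, `mean`,
#'   `variance`, `sd`, `cv` (coefficient of variation, `sd/mean`).
#' @export
normal_cost_model <- function(mean, variance, group = NA_character_) {
  check_number(mean, "mean")
  check_number(variance, "variance", min = 0)
  sd <- sqrt(variance)
  structure(
    list(group = group, mean = mean, variance = variance, sd = sd,
         cv = if (mean > 0) sd / mean else NA_real_),
    class = "normal_cost_model"
  )
}

#' @export
print.normal_cost_model <- function(x, ...) {
  cat(sprintf("<normal cost model%s>\n",
              if (is.na(x$group)) "" else paste0(": ", x$group)))
  cat(sprintf("  mean %s ZAR | sd %s ZAR | variance %s | CV %s\n",
              format(round(x$mean, 2)), format(round(x$sd, 3)),
              format(round(x$variance, 1)),
              if (is.na(x$cv)) "-" else sprintf("%.2f%%", 100 * x$cv)))
  invisible(x)
}

#' Aggregate component summaries into a total-cost model
#'
#' Sums component means and variances (components assumed independent, so no
#' covariance terms) and treats the total as normal — the central step of the
#' Symmetric Approximation.
#'
#' @param components a component summary tibble from [component_summary()]
#'   (columns `mean`, `variance`; one row per component).
#' @param group population group label carried into the model.
#' @return a [normal_cost_model()].
#' @examples
#' adult <- component_summary(table1_components("adult"))
#' aggregate_total(adult, group = "adult")
#' @export
aggregate_total <- function(components, group = NA_character_) {
  if (!is.data.frame(components) || nrow(components) == 0L) {
    abort_probcost("at least one component summary is required",
                   "probcost_input_error")
  }
  normal_cost_model(sum(components$mean), sum(components$variance), group)
}

#' Unit cost at a target probability
#'
#' The `probability`-quantile of the normal total-cost model: the unit cost
#' such that realized cost stays below it with the given probability. Strictly
#' increasing in the probability (before rounding) for positive sd.
#'
#' @param model a [normal_cost_model()].
#' @param probability probability (strictly between 0 and 1); vectorised.
#' @param round round half-up to whole ZAR (the reporting convention for
#'   published unit costs). Default `TRUE`.
#' @return unit cost(s) in ZAR.
#' @examples
#' m <- aggregate_total(component_summary(table1_components("adult")), "adult")
#' unit_cost_at_probability(m, c(0.50, 0.75, 0.90))
#' @export
unit_cost_at_probability <- function(model, probability, round = TRUE) {
  stopifnot(inherits(model, "normal_cost_model"))
  if (any(probability <= 0 | probability >= 1)) {
    abort_probcost("probability must lie strictly between 0 and 1",
                   "probcost_input_error")
  }
  q <- stats::qnorm(probability, mean = model$mean, sd = model$sd)
  if (round) round_half_up(q) else q
}

#' Fit the full Symmetric Approximation for one population group
#'
#' Convenience wrapper chaining [derive_component_ranges()],
#' [component_summary()] and [aggregate_total()].
#'
#' @inheritParams derive_component_ranges
#' @inheritParams component_summary
#' @param group population group label.
#' @return a list with elements `ranges` (three-point tibble), `components`
#'   (summary tibble with moments) and `model` (a [normal_cost_model()]).
#' @export
symmetric_approximation <- function(condition_costs, ranking,
                                    group = NA_character_,
                                    shape = "triangular") {
  ranges <- derive_component_ranges(condition_costs, ranking)
  components <- component_summary(ranges, shape = shape)
  list(ranges = ranges, components = components,
       model = aggregate_total(components, group))
}
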