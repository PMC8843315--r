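# Published reference tables used as read-only fixtures: the three-point
# component estimates for the South African 2020 NCD costing exercise, the
# provincial service-demand tables, and the 2020 clinic budget envelope.

#' Three-point component cost estimates (2020 South Africa NCD exercise)
#'
#' Per population group (adult, child) and per cost component: the low, most
#' likely and high values of the component's per-condition total cost, together
#' with the variance and mean as printed in the source table. Two printed cells
#' are known anomalies and carried as-is:
#' \itemize{
#'   \item the adult diagnostics printed mean (275) disagrees with the
#'     closed-form triangular mean of its own three points (257.27); 257 — not
#'     275 — is consistent with the printed adult total mean 3 182. Flagged via
#'     `mean_anomalous`, not silently corrected.
#'   \item small-magnitude printed variances/means are rounded to whole units
#'     in the source, so they match the closed forms only to that precision.
#' }
#'
#' @param group `"adult"`, `"child"`, or `"both"` (default).
#' @return a tibble with columns `population_group`, `component_type`, `low`,
#'   `most_likely`, `high`, `printed_variance`, `printed_mean`,
#'   `mean_anomalous`.
#' @examples
#' tab <- table1_components("adult")
#' sum(apply(tab[, c("low", "most_likely", "high")], 1, triangular_mean))
#' @export
table1_components <- function(group = c("both", "adult", "child")) {
  group <- match.arg(group)
  adult <- tibble::tibble(
    population_group = "adult",
    component_type = COMPONENT_TYPES,
    low         = c(9.04,    0.07, 0,      1.03,      0),
    most_likely = c(1768.92, 3.23, 94.30,  214.2875,  239.48875),
    high        = c(4232.67, 7.59, 677.52, 1436.34,   862.43),
    printed_variance = c(750149, 2, 22446, 99972, 33031),
    printed_mean     = c(2004,   4, 275,   551,   367),
    mean_anomalous   = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  child <- tibble::tibble(
    population_group = "child",
    component_type = COMPONENT_TYPES,
    low         = c(12.97,   0.32,   0,     0,        0),
    most_likely = c(303.81,  0.6875, 0,     48.61625, 32.535625),
    high        = c(2334.62, 4.97,   63.74, 474.61,   162.19),
    printed_variance = c(266629, 1, 226, 11363, 1227),
    printed_mean     = c(884,    2, 21,  174,   65),
    mean_anomalous   = FALSE
  )
  switch(group,
         adult = adult,
         child = child,
         both = rbind(adult, child))
}

# Printed totals row of the three-point summary table.
TABLE1_TOTALS <- list(
  adult = list(mean = 3182, variance = 905600, sd = 951.630, cv = 0.2990),
  child = list(mean = 1146, variance = 279446, sd = 528.626, cv = 0.4612)
)

#' Printed total-cost moments of the published summary table
#'
#' The totals row of [table1_components()] as printed: summed mean and
#' variance, standard deviation and coefficient of variation per population
#' group.
#'
#' @param group `"adult"` or `"child"`.
#' @return a list with elements `mean`, `variance`, `sd`, `cv`.
#' @export
table1_totals <- function(group = c("adult", "child")) {
  TABLE1_TOTALS[[match.arg(group)]]
}

#' Provincial NCD service demand tables (2020 South Africa)
#'
#' Nine provinces per population group with population, primary-health-care
#' headcount (visits), the printed utilisation rate, and the printed projected
#' services column. The printed national totals row is attached as the
#' `printed_totals` attribute; note the printed services columns carry
#' unit-level rounding, so their column sums differ from the printed totals by
#' 1 (adult) and 2 (child).
#'
#' @param group `"adult"` or `"child"`.
#' @return a tibble with columns `province`, `population`, `phc_headcount`,
#'   `utilisation`, `services`, and attribute `printed_totals` (named list
#'   with `population`, `phc_headcount`, `services`).
#' @examples
#' adults <- province_services("adult")
#' attr(adults, "printed_totals")$services
#' @export
province_services <- function(group = c("adult", "child")) {
  group <- match.arg(group)
  provinces <- c("Eastern Cape", "Free State", "Gauteng", "KwaZulu-Natal",
                 "Limpopo", "Mpumalanga", "Northern Cape", "North West",
                 "Western Cape")
  if (group == "adult") {
    out <- tibble::tibble(
      province = provinces,
      population = c(4615040, 2078879, 11797965, 7975441, 4137210,
                     3290020, 918972, 2915078, 5221073),
      phc_headcount = c(11841466, 4073217, 15689380, 20261387, 9777467,
                        6468022, 2020281, 5644648, 10689597),
      utilisation = 2,
      services = c(1337043, 602281, 2563529, 2310599, 1198609,
                   953166, 266239, 844540, 1512619)
    )
    totals <- list(population = 42949678, phc_headcount = 86465465,
                   services = 11588626)
  } else {
    out <- tibble::tibble(
      province = provinces,
      population = c(2097236, 808586, 3378151, 3313645, 1845374,
                     1302167, 344903, 1112082, 1623199),
      phc_headcount = c(2057253, 467294, 1958824, 3505659, 1630380,
                        1046369, 259492, 729783, 1588620),
      utilisation = 1,
      services = c(1063299, 409953, 1712723, 1680018, 935605,
                   660199, 174866, 563826, 822962)
    )
    totals <- list(population = 15825343, phc_headcount = 13243674,
                   services = 8023449)
  }
  attr(out, "printed_totals") <- totals
  out
}

#' National clinic-services budget envelope, 2020 financial year
#'
#' The amount budgeted by the National Treasury for clinic health services
#' across all provinces for the 2020 financial year, in ZAR. Used as the
#' default budget in the worked budget-gap comparison.
#'
#' @return a single number (ZAR).
#' @export
za_clinic_budget_2020 <- function() 19581032000
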