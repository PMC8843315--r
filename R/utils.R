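# Shared internal helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used at every reporting boundary where
#' whole-currency figures are emitted. Base R's `round()` rounds half to even,
#' which does not reproduce published budgeting tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(0.5)    # 1, where round(0.5) is 0
#' round_half_up(2.345, 2)
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# The five resource classes that make up the cost of one visit.
COMPONENT_TYPES <- c(
  "human_resources", "equipment", "diagnostics",
  "medical_consumables", "medicine"
)

# Component types consumed in full per treatment (quantity x unit price).
CONSUMED_TYPES <- c("diagnostics", "medical_consumables", "medicine")

#' Cost component types
#'
#' The five per-visit resource classes used throughout the package:
#' human resources, equipment, diagnostics, medical consumables, medicine.
#'
#' @return character vector of the five component type labels.
#' @export
component_types <- function() COMPONENT_TYPES

#' WHO NCD condition categories
#'
#' The five condition groupings used to classify non-communicable diseases:
#' cardiovascular, diabetes, chronic respiratory, cancer, and a residual
#' "other" group.
#'
#' @return character vector of the five category labels.
#' @export
ncd_categories <- function() {
  c("cardiovascular", "diabetes", "chronic_respiratory", "cancer", "other")
}

# Fail with a classed error so callers/tests can match on class.
abort_probcost <- function(msg, class) {
  stop(structure(
    class = c(class, "probcost_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_probcost(sprintf("`%s` must be a single number", name),
                   "probcost_input_error")
  }
  bad <- if (strict_min) x <= min else x < min
  if (bad) {
    cmp <- if (strict_min) ">" else ">="
    abort_probcost(sprintf("`%s` must be %s %s", name, cmp, format(min)),
                   "probcost_input_error")
  }
  invisible(x)
}

# Format whole-ZAR amounts with thousands separators (presentation only).
format_zar <- function(x) {
  formatC(x, format = "f", digits = 0, big.mark = ",")
}
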