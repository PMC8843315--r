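# Budget overrun/underrun risk for a point of estimate (POE) against the
# normal total-cost model. Two dialects: "exact" uses the normal CDF at full
# precision; "table" reproduces the classic printed standard-normal-table
# workflow (z rounded to 2 decimals, one-sided probability to 4 decimals).

#' z-value of a point of estimate
#'
#' `(poe - mean) / sd` against a normal total-cost model.
#'
#' @param poe point of estimate (ZAR): a candidate unit cost or budget figure.
#' @param model a [normal_cost_model()] with positive sd.
#' @return the standardized distance of the POE from the mean.
#' @examples
#' z_value(3824, normal_cost_model(3182, 951.630^2))  # 0.674632
#' @export
z_value <- function(poe, model) {
  stopifnot(inherits(model, "normal_cost_model"))
  if (model$sd <= 0) {
    abort_probcost("model sd must be positive to standardize a POE",
                   "probcost_input_error")
  }
  (poe - model$mean) / model$sd
}

#' Standard-normal-table probability of a z-value
#'
#' The classic one-sided table value: `pnorm(|z| rounded to 2 decimals) - 0.5`,
#' reported to 4 decimals — the probability mass between the mean and the POE.
#'
#' @param z a finite z-value.
#' @return one-sided probability in `[0, 0.5]`, to 4 decimals.
#' @examples
#' table_probability(0.674632)  # 0.2486, the table row for z = 0.67
#' @export
table_probability <- function(z) {
  round_half_up(stats::pnorm(round_half_up(abs(z), 2L)) - 0.5, 4L)
}

#' Budget overrun and underrun probabilities
#'
#' For a POE at or above the mean, the overrun probability is 50% minus the
#' one-sided probability of the z-value, and the underrun is its complement;
#' for a POE below the mean, 50% is added instead. In the exact dialect the
#' one-sided probability is `pnorm(|z|) - 0.5` at full precision; in the table
#' dialect it is [table_probability()]. Either way overrun + underrun = 1
#' before any percent rounding.
#'
#' @inheritParams z_value
#' @param dialect `"exact"` (default) or `"table"`.
#' @return an object of class `risk_result`: list with `poe`, `z`,
#'   `overrun`, `underrun` (fractions), `dialect`.
#' @examples
#' m <- normal_cost_model(3182, 951.630^2, "adult")
#' overrun_underrun(3824, m, dialect = "table")  # overrun 25%, underrun 75%
#' @export
overrun_underrun <- function(poe, model, dialect = c("exact", "table")) {
  dialect <- match.arg(dialect)
  z <- z_value(poe, model)
  tail <- switch(dialect,
                 exact = stats::pnorm(abs(z)) - 0.5,
                 table = table_probability(z))
  overrun <- if (poe >= model$mean) 0.5 - tail else 0.5 + tail
  structure(
    list(poe = poe, z = z, overrun = overrun, underrun = 1 - overrun,
         dialect = dialect),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<budget risk, %s dialect> POE %s | z = %.6f\n",
              x$dialect, format_zar(x$poe), x$z))
  cat(sprintf("  overrun %s%% | underrun %s%%\n",
              format(round_half_up(100 * x$overrun)),
              format(round_half_up(100 * x$underrun))))
  invisible(x)
}
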