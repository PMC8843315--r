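# Three-point (triangular) cost estimates and their closed-form moments.

#' Create a three-point cost estimate
#'
#' A `(low, most likely, high)` triple characterising the uncertainty of one
#' cost component, interpreted by default as a triangular distribution on
#' `[low, high]` with mode at `most_likely`.
#'
#' @param low lowest plausible cost (ZAR).
#' @param most_likely modal cost (ZAR).
#' @param high highest plausible cost (ZAR).
#' @return an object of class `triangular_estimate`.
#' @examples
#' e <- triangular_estimate(9.04, 1768.92, 4232.67)
#' triangular_mean(e)
#' triangular_variance(e)
#' @export
triangular_estimate <- function(low, most_likely, high) {
  check_number(low, "low")
  check_number(most_likely, "most_likely")
  check_number(high, "high")
  if (low > most_likely || most_likely > high) {
    abort_probcost(
      sprintf("three-point estimate must satisfy low <= most_likely <= high (got %s, %s, %s)",
              format(low), format(most_likely), format(high)),
      "probcost_estimate_error"
    )
  }
  structure(
    list(low = low, most_likely = most_likely, high = high),
    class = "triangular_estimate"
  )
}

#' @export
print.triangular_estimate <- function(x, ...) {
  cat(sprintf("<triangular estimate> low %s | most likely %s | high %s\n",
              format(x$low), format(x$most_likely), format(x$high)))
  invisible(x)
}

as_triangular <- function(x) {
  if (inherits(x, "triangular_estimate")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(triangular_estimate(x[[1L]], x[[2L]], x[[3L]]))
  }
  abort_probcost("expected a triangular_estimate or a numeric triple",
                 "probcost_input_error")
}

#' Mean of a triangular distribution
#'
#' `(low + most_likely + high) / 3`.
#'
#' @param e a [triangular_estimate()] (or numeric triple).
#' @return the distribution mean (ZAR).
#' @export
triangular_mean <- function(e) {
  e <- as_triangular(e)
  (e$low + e$most_likely + e$high) / 3
}

#' Variance of a triangular distribution
#'
#' Closed form `(l^2 + m^2 + h^2 - l*m - l*h - m*h) / 18`; zero exactly when
#' the three points coincide.
#'
#' @inheritParams triangular_mean
#' @return the distribution variance (ZAR^2).
#' @export
triangular_variance <- function(e) {
  e <- as_triangular(e)
  l <- e$low; m <- e$most_likely; h <- e$high
  (l^2 + m^2 + h^2 - l * m - l * h - m * h) / 18
}

#' Quantile function of a triangular distribution
#'
#' Closed-form inverse CDF, the basis of the inverse-transform sampler used by
#' the Monte Carlo oracle.
#'
#' @inheritParams triangular_mean
#' @param p vector of probabilities in `[0, 1]`.
#' @return quantiles of the triangular distribution at `p`.
#' @export
triangular_quantile <- function(e, p) {
  e <- as_triangular(e)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_probcost("probabilities must lie in [0, 1]", "probcost_input_error")
  }
  l <- e$low; m <- e$most_likely; h <- e$high
  if (h == l) return(rep(l, length(p)))
  fc <- (m - l) / (h - l)  # CDF at the mode
  ifelse(p < fc,
         l + sqrt(p * (h - l) * (m - l)),
         h - sqrt((1 - p) * (h - l) * (h - m)))
}

#' Sample from a triangular distribution
#'
#' Inverse-transform sampling: exactly reproducible under a fixed RNG state,
#' no rejection step.
#'
#' @inheritParams triangular_mean
#' @param n number of draws.
#' @return numeric vector of `n` draws.
#' @export
rtriangular <- function(n, e) {
  triangular_quantile(e, stats::runif(n))
}

#' Summarise cost components under a chosen distribution shape
#'
#' Turns three-point estimates into per-component means and variances. The
#' default shape is triangular; uniform, normal and beta (PERT) are available
#' as alternative readings of the same three points:
#' \describe{
#'   \item{triangular}{mean `(l+m+h)/3`, variance `(l^2+m^2+h^2-lm-lh-mh)/18`.}
#'   \item{uniform}{ignores the mode: mean `(l+h)/2`, variance `(h-l)^2/12`.}
#'   \item{normal}{centred on the mode with the conventional six-sigma range:
#'     mean `m`, variance `((h-l)/6)^2`.}
#'   \item{beta}{the PERT approximation: mean `(l+4m+h)/6`, variance
#'     `((h-l)/6)^2`.}
#' }
#'
#' @param estimates a named list of [triangular_estimate()]s (names are
#'   component types), or a data frame with columns `component_type`, `low`,
#'   `most_likely`, `high`.
#' @param shape distribution shape assumed for every component.
#' @return a tibble with columns `component_type`, `low`, `most_likely`,
#'   `high`, `mean`, `variance`.
#' @examples
#' component_summary(list(medicine = triangular_estimate(0, 239.48875, 862.43)))
#' @export
component_summary <- function(estimates,
                              shape = c("triangular", "uniform", "normal", "beta")) {
  shape <- match.arg(shape)
  if (is.data.frame(estimates)) {
    est_list <- lapply(seq_len(nrow(estimates)), function(i) {
      triangular_estimate(estimates$low[i], estimates$most_likely[i],
                          estimates$high[i])
    })
    names(est_list) <- estimates$component_type
    estimates <- est_list
  }
  if (length(estimates) == 0L) {
    abort_probcost("at least one component estimate is required",
                   "probcost_input_error")
  }
  moments <- lapply(estimates, function(e) {
    e <- as_triangular(e)
    l <- e$low; m <- e$most_likely; h <- e$high
    switch(shape,
      triangular = c(triangular_mean(e), triangular_variance(e)),
      uniform    = c((l + h) / 2, (h - l)^2 / 12),
      normal     = c(m, ((h - l) / 6)^2),
      beta       = c((l + 4 * m + h) / 6, ((h - l) / 6)^2)
    )
  })
  tibble::tibble(
    component_type = names(estimates),
    low = vapply(estimates, function(e) as_triangular(e)$low, numeric(1),
                 USE.NAMES = FALSE),
    most_likely = vapply(estimates, function(e) as_triangular(e)$most_likely,
                         numeric(1), USE.NAMES = FALSE),
    high = vapply(estimates, function(e) as_triangular(e)$high, numeric(1),
                  USE.NAMES = FALSE),
    mean = vapply(moments, `[`, numeric(1), 1L, USE.NAMES = FALSE),
    variance = vapply(moments, `[`, numeric(1), 2L, USE.NAMES = FALSE)
  )
}
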