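# Seeded synthetic-data generator: condition treatment profiles, category
# rankings and province demand tables with known ground truth, so every
# downstream stage is testable without external data.

#' Generator configuration
#'
#' Settings for the synthetic condition-table generator. All price draws are
#' uniform within the configured range (a bounded distribution keeps
#' range-recovery by the probability-based step exact); category assignment is
#' uniform across the configured categories unless `category_counts` fixes the
#' split.
#'
#' @param n_conditions number of conditions to generate (default 58, the
#'   adult condition count of the reference treatment guidelines; use 40 for
#'   the child group).
#' @param categories condition category labels (default [ncd_categories()]).
#' @param population_group label carried on every condition (default
#'   `"adult"`).
#' @param price_ranges named list of `c(low, high)` ZAR ranges per component
#'   type; for human resources the range is of annual salaries, for equipment
#'   of acquisition costs, otherwise of per-unit prices.
#' @param visits_range integer `c(min, max)` prescribed visits per condition.
#' @param usages_range integer `c(min, max)` usages per component type per
#'   visit (0 allowed at the minimum; every visit is guaranteed at least one
#'   usage overall).
#' @param quantity_range integer `c(min, max)` units per consumed usage.
#' @param duration_range integer `c(min, max)` minutes per human-resource or
#'   equipment usage.
#' @param category_counts optional named integer vector fixing how many
#'   conditions fall in each category (must sum to `n_conditions`).
#' @param seed integer RNG seed; mandatory, generation is seed-deterministic.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_conditions = 58,
                             categories = ncd_categories(),
                             population_group = "adult",
                             price_ranges = default_price_ranges(),
                             visits_range = c(1L, 6L),
                             usages_range = c(1L, 2L),
                             quantity_range = c(1L, 3L),
                             duration_range = c(5L, 30L),
                             category_counts = NULL,
                             seed = 1L) {
  check_number(n_conditions, "n_conditions", min = 1)
  check_number(seed, "seed")
  if (length(categories) == 0L) {
    abort_probcost("at least one category label is required",
                   "probcost_config_error")
  }
  if (anyDuplicated(categories)) {
    abort_probcost("duplicate category labels", "probcost_config_error")
  }
  missing <- setdiff(COMPONENT_TYPES, names(price_ranges))
  if (length(missing)) {
    abort_probcost(sprintf("price range missing for: %s",
                           paste(missing, collapse = ", ")),
                   "probcost_config_error")
  }
  for (ct in COMPONENT_TYPES) {
    r <- price_ranges[[ct]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 0) {
      abort_probcost(sprintf("invalid price range for %s: need 0 <= low <= high", ct),
                     "probcost_config_error")
    }
  }
  for (nm in c("visits_range", "usages_range", "quantity_range",
               "duration_range")) {
    r <- get(nm)
    if (length(r) != 2L || r[1L] > r[2L]) {
      abort_probcost(sprintf("`%s` must be c(min, max) with min <= max", nm),
                     "probcost_config_error")
    }
  }
  if (visits_range[1L] < 1L) {
    abort_probcost("every condition needs at least one visit",
                   "probcost_config_error")
  }
  if (!is.null(category_counts)) {
    if (!setequal(names(category_counts), categories) ||
        sum(category_counts) != n_conditions) {
      abort_probcost("category_counts must name every category and sum to n_conditions",
                     "probcost_config_error")
    }
  }
  structure(
    list(n_conditions = as.integer(n_conditions), categories = categories,
         population_group = population_group, price_ranges = price_ranges,
         visits_range = as.integer(visits_range),
         usages_range = as.integer(usages_range),
         quantity_range = as.integer(quantity_range),
         duration_range = as.integer(duration_range),
         category_counts = category_counts, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default synthetic price ranges
#'
#' Order-of-magnitude ZAR ranges per component type used by the generator
#' when none are configured: annual salaries for human resources, acquisition
#' costs for equipment, per-unit prices otherwise.
#'
#' @return named list of `c(low, high)` ranges.
#' @export
default_price_ranges <- function() {
  list(
    human_resources = c(180000, 900000),   # annual salary, ZAR/yr
    equipment = c(500, 150000),            # acquisition cost, ZAR
    diagnostics = c(0, 700),               # per test, ZAR
    medical_consumables = c(0, 1500),      # per unit, ZAR
    medicine = c(0, 900)                   # per course, ZAR
  )
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

sample_int <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Generate a synthetic condition table
#'
#' Emits a long-format condition table: one row per component usage, with the
#' columns consumed by [condition_cost_table()]. Each condition carries one
#' category and one population-group label, has at least one visit, and each
#' visit at least one usage; prices are drawn uniformly inside the configured
#' ranges. Identical config (including seed) reproduces the table exactly.
#'
#' @param config a [generator_config()].
#' @return a tibble with columns `condition_id`, `category`,
#'   `population_group`, `visit_index`, `component_type`, `quantity`,
#'   `unit_price`, `duration_min`.
#' @examples
#' head(generate_condition_table(generator_config(n_conditions = 3, seed = 7)))
#' @export
generate_condition_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_rng(config$seed, {
    cats <- if (is.null(config$category_counts)) {
      sample(config$categories, config$n_conditions, replace = TRUE)
    } else {
      sample(rep(names(config$category_counts), config$category_counts))
    }
    rows <- vector("list", config$n_conditions)
    for (i in seq_len(config$n_conditions)) {
      n_visits <- sample_int(config$visits_range)
      visit_rows <- list()
      for (v in seq_len(n_visits)) {
        for (ct in COMPONENT_TYPES) {
          n_use <- sample_int(config$usages_range)
          if (n_use == 0L) next
          r <- config$price_ranges[[ct]]
          consumed <- ct %in% CONSUMED_TYPES
          visit_rows[[length(visit_rows) + 1L]] <- tibble::tibble(
            visit_index = v,
            component_type = ct,
            quantity = if (consumed) sample_int(config$quantity_range, n_use)
                       else rep(1L, n_use),
            unit_price = stats::runif(n_use, r[1L], r[2L]),
            duration_min = if (consumed) rep(0L, n_use)
                           else sample_int(config$duration_range, n_use)
          )
        }
        # every visit must consume something; fall back to one consumable
        if (!length(visit_rows) ||
            max(vapply(visit_rows, function(x) x$visit_index[1L], numeric(1))) < v) {
          r <- config$price_ranges[["medical_consumables"]]
          visit_rows[[length(visit_rows) + 1L]] <- tibble::tibble(
            visit_index = v, component_type = "medical_consumables",
            quantity = 1L, unit_price = stats::runif(1, r[1L], r[2L]),
            duration_min = 0L
          )
        }
      }
      cond <- do.call(rbind, visit_rows)
      cond <- tibble::tibble(
        condition_id = sprintf("C%03d", i),
        category = cats[i],
        population_group = config$population_group,
        cond
      )
      rows[[i]] <- cond
    }
    do.call(rbind, rows)
  })
}

#' Generate (or pass through) a category ranking
#'
#' Stands in for the expert-elicitation step that orders condition categories
#' from most to least frequently treated. With `override` supplied, the
#' ranking is returned verbatim (after a duplicate check); otherwise a
#' seed-deterministic random permutation of `categories` is drawn.
#'
#' @param categories category labels to rank.
#' @param seed integer RNG seed (ignored when `override` is given).
#' @param override optional user-supplied ranking, returned unchanged.
#' @return ordered character vector, most frequently treated category first.
#' @examples
#' generate_category_ranking(ncd_categories(), seed = 3)
#' generate_category_ranking(override = c("cardiovascular", "diabetes",
#'   "chronic_respiratory", "cancer", "other"))
#' @export
generate_category_ranking <- function(categories = ncd_categories(),
                                      seed = 1L, override = NULL) {
  ranking <- if (!is.null(override)) override
             else {
               if (length(categories) == 0L) {
                 abort_probcost("at least one category label is required",
                                "probcost_config_error")
               }
               with_preserved_rng(seed, sample(categories))
             }
  if (anyDuplicated(ranking)) {
    abort_probcost("duplicate category labels in ranking",
                   "probcost_config_error")
  }
  ranking
}

#' Generate a synthetic province demand table
#'
#' Emulates the structure of a provincial service-demand table: population,
#' primary-care headcount (population x utilisation with noise), utilisation
#' rate and a services column derived from the headcount.
#'
#' @param n_provinces number of provinces (default 9).
#' @param population_range `c(min, max)` population per province.
#' @param utilisation_range integer `c(min, max)` visits/person/period.
#' @param visits_per_episode average visits per treatment episode used to
#'   derive the services column from the headcount.
#' @param seed integer RNG seed.
#' @return a tibble with columns `province`, `population`, `phc_headcount`,
#'   `utilisation`, `services`.
#' @export
generate_province_table <- function(n_provinces = 9,
                                    population_range = c(3e5, 1.2e7),
                                    utilisation_range = c(1L, 3L),
                                    visits_per_episode = 7,
                                    seed = 1L) {
  check_number(n_provinces, "n_provinces", min = 1)
  check_number(visits_per_episode, "visits_per_episode", min = 0,
               strict_min = TRUE)
  with_preserved_rng(seed, {
    population <- round(stats::runif(n_provinces, population_range[1L],
                                     population_range[2L]))
    utilisation <- sample_int(as.integer(utilisation_range), n_provinces)
    headcount <- round(population * utilisation *
                         stats::runif(n_provinces, 0.8, 1.3))
    tibble::tibble(
      province = sprintf("Province %02d", seq_len(n_provinces)),
      population = population,
      phc_headcount = headcount,
      utilisation = utilisation,
      services = round_half_up(headcount / visits_per_episode)
    )
  })
}

#' Write / read a condition table as CSV
#'
#' Plain CSV with a header row and the documented column set
#' (`condition_id`, `category`, `population_group`, `visit_index`,
#' `component_type`, `quantity`, `unit_price`, `duration_min`).
#'
#' @param conditions a condition table tibble.
#' @param path file path.
#' @return `write_condition_csv()` returns `path` invisibly;
#'   `read_condition_csv()` returns the tibble.
#' @export
write_condition_csv <- function(conditions, path) {
  utils::write.csv(conditions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_csv
#' @export
read_condition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition_id", "category", "population_group", "visit_index",
              "component_type", "quantity", "unit_price", "duration_min")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort_probcost(sprintf("condition CSV %s lacks column(s): %s",
                           path, paste(missing, collapse = ", ")),
                   "probcost_io_error")
  }
  tibble::as_tibble(df)
}
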