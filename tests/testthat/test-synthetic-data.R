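test_that("generation is seed-deterministic, byte-for-byte after serialization", {
  cfg <- generator_config(n_conditions = 58, seed = 7)
  a <- generate_condition_table(cfg)
  b <- generate_condition_table(cfg)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_condition_csv(a, fa); write_condition_csv(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # a different seed changes the table
  expect_false(identical(
    a, generate_condition_table(generator_config(n_conditions = 58, seed = 8))))
})

test_that("generated tables respect the configured structure", {
  cfg <- generator_config(n_conditions = 20, seed = 3,
                          visits_range = c(1L, 4L))
  tab <- generate_condition_table(cfg)
  expect_equal(length(unique(tab$condition_id)), 20L)
  per_cond <- split(tab, tab$condition_id)
  for (df in per_cond) {
    expect_length(unique(df$category), 1L)
    expect_length(unique(df$population_group), 1L)
    expect_gte(min(df$visit_index), 1L)
    # every visit has at least one usage
    expect_setequal(unique(df$visit_index), seq_len(max(df$visit_index)))
  }
  expect_true(all(tab$category %in% ncd_categories()))
  expect_true(all(tab$component_type %in% component_types()))
  expect_true(all(tab$quantity >= 0) && all(tab$unit_price >= 0))
})

test_that("degenerate zero price ranges yield a zero-cost condition", {
  zero_ranges <- stats::setNames(rep(list(c(0, 0)), 5), component_types())
  cfg <- generator_config(n_conditions = 1, seed = 1,
                          price_ranges = zero_ranges,
                          visits_range = c(1L, 1L))
  tab <- generate_condition_table(cfg)
  cc <- condition_unit_cost(tab, toy_bases())
  expect_equal(cc$total, 0)
})

test_that("all drawn prices and consumed totals stay inside the configured range", {
  ranges <- stats::setNames(rep(list(c(10, 20)), 5), component_types())
  cfg <- generator_config(n_conditions = 500, seed = 12,
                          price_ranges = ranges, quantity_range = c(1L, 1L))
  tab <- generate_condition_table(cfg)
  expect_true(all(tab$unit_price >= 10 & tab$unit_price <= 20))
  # brute-force range check: each consumed component total lies within
  # [10 * n_usages, 20 * n_usages]
  consumed <- tab[tab$component_type %in%
                    c("diagnostics", "medical_consumables", "medicine"), ]
  key <- interaction(consumed$condition_id, consumed$component_type)
  totals <- tapply(consumed$quantity * consumed$unit_price, key, sum)
  usages <- tapply(rep(1, nrow(consumed)), key, sum)
  keep <- !is.na(totals)
  expect_true(all(totals[keep] >= 10 * usages[keep]))
  expect_true(all(totals[keep] <= 20 * usages[keep]))
})

test_that("range derivation recovers the generator's ground truth", {
  cfg <- generator_config(n_conditions = 40, seed = 21,
                          population_group = "child")
  costs <- condition_cost_table(generate_condition_table(cfg), toy_bases())
  ranking <- generate_category_ranking(unique(costs$category), seed = 5)
  ranges <- derive_component_ranges(costs, ranking)
  for (i in seq_len(nrow(ranges))) {
    totals <- costs$total[costs$component_type == ranges$component_type[i]]
    expect_identical(ranges$low[i], min(totals))
    expect_identical(ranges$high[i], max(totals))
  }
})

test_that("category rankings permute, honour overrides and reject duplicates", {
  cats <- ncd_categories()
  r <- generate_category_ranking(cats, seed = 9)
  expect_setequal(r, cats)
  expect_identical(r, generate_category_ranking(cats, seed = 9))
  expect_identical(generate_category_ranking("cardiovascular", seed = 1),
                   "cardiovascular")
  # adult and child overrides pass through verbatim
  adult_rank <- c("cardiovascular", "diabetes", "chronic_respiratory",
                  "cancer", "other")
  expect_identical(generate_category_ranking(override = adult_rank),
                   adult_rank)
  child_rank <- c("other", "cardiovascular", "diabetes",
                  "chronic_respiratory", "cancer")
  expect_identical(generate_category_ranking(override = child_rank)[1],
                   "other")
  expect_error(generate_category_ranking(override = c("a", "a")),
               class = "probcost_config_error")
})

test_that("invalid generator configurations fail fast", {
  expect_error(generator_config(categories = character(0)),
               class = "probcost_config_error")
  bad <- default_price_ranges(); bad$medicine <- c(20, 10)
  expect_error(generator_config(price_ranges = bad),
               class = "probcost_config_error")
  expect_error(generator_config(n_conditions = 0),
               class = "probcost_input_error")
  expect_error(generator_config(category_counts = c(cardiovascular = 58)),
               class = "probcost_config_error")
})

test_that("condition CSVs round-trip through write/read", {
  tab <- generate_condition_table(generator_config(n_conditions = 5, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_condition_csv(tab, path)
  back <- read_condition_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  broken <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), broken, row.names = FALSE)
  expect_error(read_condition_csv(broken), class = "probcost_io_error")
})

test_that("synthetic province tables are seeded and internally consistent", {
  p <- generate_province_table(seed = 4)
  expect_identical(p, generate_province_table(seed = 4))
  expect_equal(nrow(p), 9L)
  expect_true(all(p$services >= 0))
  agg <- aggregate_provinces(p)
  expect_equal(agg$population, sum(p$population))
})
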