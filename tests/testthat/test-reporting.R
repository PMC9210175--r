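# Pipeline orchestration, gaps, severity patterns, prioritisation, I/O.

small_bundle <- function(n = 1200, seed = 14L, ...) {
  run_pipeline(synthetic_scenario(n = n, seed = seed, ...))
}

test_that("the pipeline emits complete, percentage-consistent tables and a run log", {
  b <- small_bundle()
  expect_s3_class(b, "inclusion_bundle")
  # table shapes: 9 domains x 6 groups, 32 indicators x 6, 9 x 4 affect
  expect_equal(length(unique(b$domain_table$unit)), 9L)
  expect_equal(length(unique(b$domain_table$group)), 6L)
  expect_equal(length(unique(b$indicator_table$unit)), 32L)
  expect_equal(length(unique(b$affect_table$group)), 4L)
  for (tab in list(b$domain_table, b$indicator_table, b$affect_table)) {
    sums <- tapply(tab$weighted_pct, list(tab$unit, tab$group), sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
    p <- tab$adjusted_p
    expect_true(all(is.na(p) | (p >= 0 & p <= 1)))
  }
  expect_equal(b$log$n_input, b$log$n_analysed + b$log$n_dropped_severity)
  expect_true(b$log$raking$converged)
})

test_that("two runs with the same scenario and seed produce identical bundles on disk", {
  b1 <- small_bundle(n = 500)
  b2 <- small_bundle(n = 500)
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in c("domain_table.csv", "indicator_table.csv", "affect_table.csv",
              "gaps.csv", "patterns.csv", "rankings.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("gap summaries recompute male minus female and name the worse-off gender", {
  tab <- data.frame(
    unit = "personal_safety",
    group = c("none:male", "none:female"),
    category = "included",
    weighted_pct = c(24.7, 13.7),
    raw_p = 0.001, adjusted_p = 0.009,
    severity = "none", gender = c("male", "female"))
  g <- compute_gaps(tab, metric = "inclusion_pct")
  expect_equal(g$gap, 11.0)
  expect_identical(g$worse_off, "female")
  tab$weighted_pct <- c(30, 30)
  g0 <- compute_gaps(tab, metric = "inclusion_pct")
  expect_equal(g0$gap, 0)
  expect_true(is.na(g0$worse_off))
  # single-gender table: skipped with a warning, empty result
  solo <- tab[tab$gender == "male", ]
  expect_warning(g1 <- compute_gaps(solo), "missing a gender")
  expect_equal(nrow(g1), 0L)
})

test_that("severity patterns follow the ordering, band and significance rules", {
  e <- c(none = 5, mild = 15, moderate = 30)
  expect_identical(classify_severity_pattern(e, 0.001), "monotone_worsening")
  e2 <- c(none = 5, mild = 22, moderate = 23)
  expect_identical(classify_severity_pattern(e2, 0.001, band = 2),
                   "mild_equals_moderate_worse")
  expect_identical(classify_severity_pattern(e, 1), "no_significant_difference")
  expect_identical(classify_severity_pattern(e, NA), "no_significant_difference")
  e3 <- c(none = 20, mild = 30, moderate = 10)
  expect_identical(classify_severity_pattern(e3, 0.001), "mild_worst")
  e4 <- c(none = 40, mild = 10, moderate = 12)
  expect_identical(classify_severity_pattern(e4, 0.001), "none_worst")
  expect_error(classify_severity_pattern(c(none = 1, mild = 2), 0.5),
               "pattern undefined")
})

test_that("prioritisation ranks are permutations with deterministic tie-breaks", {
  b <- small_bundle(n = 800, seed = 15L)
  for (a in names(b$rankings)) {
    r <- b$rankings[[a]]
    if (a == "closest_to_inclusion") {
      expect_true(all(r$domain %in% names(inclusion_domains)))
    } else {
      expect_setequal(r$domain, names(inclusion_domains))
    }
    expect_equal(r$rank, seq_len(nrow(r)))
  }
  # constructed 30-point gap puts that domain first
  tab <- expand.grid(unit = c("d_a", "d_b"),
                     severity = c("none", "mild", "moderate"),
                     gender = c("male", "female"),
                     category = inclusion_categories,
                     stringsAsFactors = FALSE)
  tab$group <- paste(tab$severity, tab$gender, sep = ":")
  tab$weighted_pct <- ifelse(tab$category == "included", 50,
                             ifelse(tab$category == "in_between", 30, 20))
  big_gap <- tab$unit == "d_b" & tab$category == "included" &
    tab$severity != "none"
  tab$weighted_pct[big_gap] <- 20
  tab$weighted_pct[tab$unit == "d_b" & tab$category == "excluded" &
                     tab$severity != "none"] <- 50
  r <- prioritise_domains(tab, "largest_disability_gap")
  expect_identical(r$domain[1], "d_b")
  expect_equal(r$score[1], 30)
  # all-identical domains: full tie, flagged, alphabetical order
  tab_same <- tab
  tab_same$weighted_pct[tab_same$category == "included"] <- 50
  tab_same$weighted_pct[tab_same$category == "in_between"] <- 30
  tab_same$weighted_pct[tab_same$category == "excluded"] <- 20
  r3 <- prioritise_domains(tab_same, "farthest_from_inclusion")
  expect_true(all(r3$tied))
  expect_identical(r3$domain, sort(r3$domain))
  expect_error(prioritise_domains(tab, "nonsense"))
})

test_that("farthest_from_inclusion puts the lowest-inclusion domains first on calibrated synthetic output", {
  # scenario shaped like the study's headline pattern: personal safety and
  # social relationships have far the lowest inclusion
  b <- small_bundle(n = 2000, seed = 16L)
  dt <- b$domain_table
  low <- c("personal_safety", "social_relationships")
  is_low <- dt$unit %in% low
  dt$weighted_pct[is_low & dt$category == "included"] <- 0.5
  dt$weighted_pct[is_low & dt$category == "excluded"] <- 0.5
  dt$weighted_pct[is_low & dt$category == "in_between"] <- 99
  r <- prioritise_domains(dt, "farthest_from_inclusion")
  expect_setequal(r$domain[1:2], low)
})

test_that("an all-included population yields 100% inclusion in every domain and group", {
  sc <- synthetic_scenario(
    n = 400, seed = 17L, refusal_rate = 0,
    indicator_probs = matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 1), nrow = 3,
                             dimnames = list(disability_severity_levels,
                                             inclusion_categories)))
  b <- run_pipeline(sc)
  inc <- b$domain_table[b$domain_table$category == "included", ]
  expect_true(all(inc$weighted_pct == 100))
})

test_that("microdata and config round-trip through CSV and JSON", {
  pop <- generate_population(synthetic_scenario(n = 50, seed = 18L))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(pop, f, row.names = FALSE, fileEncoding = "UTF-8")
  back <- read_microdata(f)
  expect_equal(back$ind_food_security, pop$ind_food_security)
  expect_equal(nrow(back), 50L)

  cfg_path <- tempfile(fileext = ".json")
  write_pipeline_config(cfg_path)
  cfg <- read_pipeline_config(cfg_path)
  expect_length(cfg$configs, 32L)
  expect_identical(cfg$settings$method, "pearson_effective_n")
  expect_identical(
    vapply(cfg$configs, `[[`, character(1L), "mode"),
    vapply(default_indicator_configs(), `[[`, character(1L), "mode"))
})
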