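# Weighted contingency tables, design-corrected chi-squared, Bonferroni.

test_that("contingency table cells are weight sums, order-invariant, zero cells allowed", {
  cats <- c("included", "excluded", "included", "in_between")
  grp <- c("a", "a", "b", "b")
  w <- c(1, 2, 3, 4)
  tab <- contingency_table(cats, w, grp)
  expect_equal(tab["a", "included"], 1)
  expect_equal(tab["a", "excluded"], 2)
  expect_equal(tab["b", "included"], 3)
  expect_equal(tab["b", "in_between"], 4)
  expect_equal(tab["b", "excluded"], 0)
  perm <- sample(4)
  expect_equal(contingency_table(cats[perm], w[perm], grp[perm]), tab)
  # unit weights give ordinary cross-tabulation
  set.seed(31)
  mi <- random_micro(100, weighted = FALSE)
  tab2 <- contingency_table(mi$categories, mi$weights, mi$groups)
  expect_equal(unclass(tab2),
               unclass(table(mi$groups, inclusion_factor(mi$categories))),
               ignore_attr = TRUE)
  expect_error(contingency_table("included", 1, "a"), "fewer than 2")
})

test_that("identical group distributions give statistic 0 and p = 1", {
  cats <- rep(c("included", "excluded"), times = 2)
  grp <- rep(c("a", "b"), each = 2)
  r <- chisq_test_weighted(cats, rep(1, 4), grp)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("with unit weights the effective-n test equals the classical Pearson chi-squared", {
  set.seed(32)
  for (rep in 1:25) {
    mi <- random_micro(150, n_groups = sample(2:4, 1L), weighted = FALSE)
    r <- chisq_test_weighted(mi$categories, mi$weights, mi$groups)
    tab <- table(mi$groups, mi$categories)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    classical <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(classical$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, unname(classical$p.value), tolerance = 1e-10)
  }
})

test_that("weighted tables match a straight-line recomputation of the rescaled Pearson formula", {
  set.seed(33)
  for (rep in 1:10) {
    mi <- random_micro(200, n_groups = 3L)
    r <- chisq_test_weighted(mi$categories, mi$weights, mi$groups)
    # independent recomputation from first principles
    w <- mi$weights
    neff <- sum(w)^2 / sum(w^2)
    tab <- tapply(w, list(mi$groups, inclusion_factor(mi$categories)),
                  sum, default = 0)
    scaled <- tab * neff / sum(tab)
    stat <- 0
    for (i in seq_len(nrow(scaled)))
      for (j in seq_len(ncol(scaled))) {
        e <- sum(scaled[i, ]) * sum(scaled[, j]) / sum(scaled)
        stat <- stat + (scaled[i, j] - e)^2 / e
      }
    p <- stats::pchisq(stat, (nrow(scaled) - 1) * (ncol(scaled) - 1),
                       lower.tail = FALSE)
    expect_equal(r$p_value, p, tolerance = 1e-10)
    expect_equal(r$effective_n, neff, tolerance = 1e-12)
    expect_lte(r$effective_n, 200)
  }
})

test_that("the rao_scott flavour uses per-group effective sizes and agrees under equal weights", {
  set.seed(34)
  mi <- random_micro(200, n_groups = 3L, weighted = FALSE)
  a <- chisq_test_weighted(mi$categories, mi$weights, mi$groups,
                           method = "pearson_effective_n")
  b <- chisq_test_weighted(mi$categories, mi$weights, mi$groups,
                           method = "rao_scott")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # unequal weights concentrated in one group shrink that group's contribution
  mi2 <- random_micro(300, n_groups = 2L)
  r2 <- chisq_test_weighted(mi2$categories, mi2$weights, mi2$groups,
                            method = "rao_scott")
  expect_true(is.finite(r2$statistic))
  expect_lte(r2$effective_n, 300)
})

test_that("degenerate tables report not-available rather than a number", {
  # single non-empty column after dropping all-zero categories
  r <- chisq_test_weighted(rep("included", 6), rep(1, 6),
                           rep(c("a", "b"), 3))
  expect_true(is.na(r$p_value))
  expect_true(is.na(r$statistic))
})

test_that("bonferroni adjustment is min(1, p * m), order-preserving, NA-passing", {
  expect_equal(bonferroni_adjust(0.001, m = 9), 0.009)
  expect_equal(bonferroni_adjust(0.2, m = 9), 1)
  expect_equal(bonferroni_adjust(0, m = 1000), 0)
  p <- c(0.04, 0.001, NA, 0.5)
  adj <- bonferroni_adjust(p, m = 9)
  expect_equal(adj, c(0.36, 0.009, NA, 1))
  expect_identical(order(p[c(1, 2, 4)]), order(adj[c(1, 2, 4)]))
  expect_true(all(adj >= p, na.rm = TRUE))
  expect_equal(bonferroni_adjust(p, m = 1), p)  # m = 1 leaves p unchanged
  expect_error(bonferroni_adjust(1.2), "0, 1")
  expect_error(bonferroni_adjust(0.5, m = 0), "at least 1")
})

test_that("run_family keeps undefined members, adjusts across the family, and defaults m to family size", {
  set.seed(35)
  n <- 120
  grp <- rep(c("a", "b"), each = n / 2)
  units <- data.frame(
    u1 = sample(inclusion_categories, n, replace = TRUE),
    u2 = rep("included", n),                      # degenerate
    u3 = sample(inclusion_categories, n, replace = TRUE))
  fam <- run_family(units, rep(1, n), grp)
  expect_s3_class(fam, "comparison_family")
  expect_equal(fam$m, 3L)
  expect_equal(nrow(fam$summary), 3L)
  expect_true(is.na(fam$summary$raw_p[fam$summary$unit == "u2"]))
  ok <- !is.na(fam$summary$raw_p)
  expect_equal(fam$summary$adjusted_p[ok],
               pmin(1, fam$summary$raw_p[ok] * 3))
})

test_that("a large planted single-domain effect is detected with high power", {
  base <- null_scenario(synthetic_scenario(n = 5000, seed = 1L))
  eff <- matrix(c(0.40, 0.25, 0.15, 0.20, 0.20, 0.15, 0.40, 0.55, 0.70),
                nrow = 3,
                dimnames = list(disability_severity_levels,
                                inclusion_categories))
  base$indicator_prob_overrides <- stats::setNames(
    rep(list(eff), 3), c("schooling", "basic_literacy", "basic_numeracy"))
  r <- simulate_rejections(base, n_replicates = 20L, seed = 2L)
  expect_gt(r$unit_rates[["education"]], 0.9)
  # untouched domains stay near the nominal level
  expect_lte(max(r$unit_rates[names(r$unit_rates) != "education"]), 0.2)
})
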