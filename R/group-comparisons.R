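# Weighted group x category tables, design-corrected chi-squared tests,
# Bonferroni adjustment, and test families.

#' Weighted group-by-category contingency table
#'
#' Cell = sum of the weights of respondents in that (group, category) cell.
#' Respondents with `NA` category are dropped. Zero cells are permitted.
#'
#' @param categories inclusion categories (NA allowed).
#' @param weights positive weights.
#' @param groups group labels.
#' @return Numeric matrix, groups in rows, the three inclusion categories in
#'   columns.
#' @export
contingency_table <- function(categories, weights, groups) {
  stopifnot(length(categories) == length(weights),
            length(groups) == length(categories))
  cat <- inclusion_factor(categories)
  keep <- !is.na(cat)
  g <- factor(groups[keep])
  if (nlevels(g) < 2L)
    stop("comparison undefined: fewer than 2 non-empty groups", call. = FALSE)
  tab <- tapply(weights[keep], list(g, cat[keep]), sum, default = 0)
  matrix(tab, nrow = nlevels(g),
         dimnames = list(levels(g), inclusion_categories))
}

# Pearson chi-squared on a (possibly non-integer) table of counts
pearson_statistic <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - expected)^2 / expected),
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

#' Kish effective sample size
#'
#' `(sum w)^2 / sum(w^2)`: the size of a simple random sample carrying the
#' same information as the weighted sample. Equals `length(w)` under equal
#' weights.
#'
#' @param w positive weights.
#' @export
effective_n <- function(w) sum(w)^2 / sum(w^2)

#' Design-corrected chi-squared test of homogeneity on a weighted table
#'
#' Two flavours. `pearson_effective_n` (default) rescales the weighted table
#' so that its total equals the Kish effective sample size of the full weight
#' vector, then applies the ordinary Pearson chi-squared test — a transparent,
#' conservative first-order correction for unequal weighting. `rao_scott`
#' rescales each group's row to that group's own effective sample size, a
#' first-order correction using per-group design effects.
#'
#' All-zero rows and columns (category never observed in any group) are
#' dropped before testing, mirroring reporting practice where such categories
#' show no entry. A table reduced below 2 x 2 has no defined test and returns
#' `NA` (reported as not-available downstream).
#'
#' The asymptotic chi-squared reference is unreliable when expected counts are
#' small (Cochran's rule of thumb: below about 5) — common here, since some
#' inclusion categories are rare in small severity-by-gender groups. With
#' `exact = "auto"` (default) the p-value then comes from the Monte Carlo
#' conditional (given margins) distribution of the statistic on the rescaled
#' table, as in `chisq.test(..., simulate.p.value = TRUE)`; otherwise the
#' asymptotic reference is used. Monte Carlo p-values consume the R random
#' stream, so seed the session (or run inside the seeded pipeline) for
#' reproducible output.
#'
#' @param categories,weights,groups respondent-level vectors as in
#'   [contingency_table()].
#' @param method `"pearson_effective_n"` or `"rao_scott"`.
#' @param exact `"auto"` (Monte Carlo reference when any expected rescaled
#'   count is below `min_expected`), `"never"`, or `"always"`.
#' @param B Monte Carlo replicates for the exact reference.
#' @param min_expected expected-count threshold triggering the exact
#'   reference under `"auto"`.
#' @return A list with `statistic`, `df` (NA under the Monte Carlo reference),
#'   `p_value` (NA when degenerate), `method`, `exact` (logical: reference
#'   used), `effective_n`, and the weighted `table`.
#' @export
chisq_test_weighted <- function(categories, weights, groups,
                                method = c("pearson_effective_n", "rao_scott"),
                                exact = c("auto", "never", "always"),
                                B = 2000L, min_expected = 5) {
  method <- match.arg(method)
  exact <- match.arg(exact)
  tab <- contingency_table(categories, weights, groups)
  keep <- !is.na(inclusion_factor(categories))
  w <- weights[keep]
  g <- factor(groups[keep])
  na_result <- function() list(statistic = NA_real_, df = NA_integer_,
                               p_value = NA_real_, method = method,
                               exact = NA, effective_n = NA_real_, table = tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(na_result())
  if (method == "pearson_effective_n") {
    neff <- effective_n(w)
    scaled <- tab * neff / sum(tab)
  } else {
    neff_g <- vapply(split(w, g)[rownames(tab)], effective_n, numeric(1L))
    scaled <- tab * neff_g / rowSums(tab)
    neff <- sum(neff_g)
  }
  expected <- outer(rowSums(scaled), colSums(scaled)) / sum(scaled)
  use_exact <- switch(exact, never = FALSE, always = TRUE,
                      auto = min(expected) < min_expected)
  if (use_exact) {
    counts <- round(scaled)
    counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
    if (nrow(counts) < 2L || ncol(counts) < 2L) return(na_result())
    ct <- suppressWarnings(stats::chisq.test(counts, simulate.p.value = TRUE,
                                             B = B))
    return(list(statistic = unname(ct$statistic), df = NA_integer_,
                p_value = unname(ct$p.value), method = method, exact = TRUE,
                effective_n = neff, table = tab))
  }
  st <- pearson_statistic(scaled)
  list(statistic = st$statistic, df = st$df,
       p_value = stats::pchisq(st$statistic, st$df, lower.tail = FALSE),
       method = method, exact = FALSE, effective_n = neff, table = tab)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise; order-preserving; `NA` (not-available tests)
#' pass through.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param m number of comparisons in the family; may exceed
#'   `length(p_values)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  pmin(1, p_values * m)
}

#' Run a family of group comparisons
#'
#' One test per analysis unit (domain or indicator): builds the weighted
#' group x category table, tests it, and Bonferroni-adjusts the raw p-values
#' across the family. Undefined tests (degenerate tables) stay in the family
#' as not-available; the family never silently shrinks.
#'
#' @param unit_categories data frame, one inclusion-category column per unit
#'   (domains from [aggregate_domains()] or indicators from
#'   [build_indicator_matrix()]).
#' @param weights respondent weights.
#' @param groups respondent group labels (e.g. severity x gender).
#' @param method test flavour, see [chisq_test_weighted()].
#' @param m family size for the adjustment; defaults to the number of units.
#' @param exact,B reference-distribution controls, see
#'   [chisq_test_weighted()].
#' @return An object of class `comparison_family`: list with `tests` (named
#'   list of test results), `summary` (data frame: unit, raw and adjusted p),
#'   `m`, `method`.
#' @export
run_family <- function(unit_categories, weights, groups,
                       method = c("pearson_effective_n", "rao_scott"),
                       m = ncol(unit_categories),
                       exact = c("auto", "never", "always"), B = 2000L) {
  method <- match.arg(method)
  exact <- match.arg(exact)
  tests <- lapply(unit_categories, function(col)
    chisq_test_weighted(col, weights, groups, method = method,
                        exact = exact, B = B))
  raw <- vapply(tests, `[[`, numeric(1L), "p_value")
  adj <- bonferroni_adjust(raw, m = m)
  structure(list(tests = tests,
                 summary = data.frame(unit = names(tests), raw_p = unname(raw),
                                      adjusted_p = unname(adj),
                                      row.names = NULL),
                 m = m, method = method),
            class = "comparison_family")
}

#' @export
print.comparison_family <- function(x, ...) {
  cat("Comparison family:", length(x$tests), "tests,",
      x$method, "chi-squared, Bonferroni m =", x$m, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}
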