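# Independent straight-line oracles, written from the published rule texts
# and kept deliberately naive (per-case loops, no shared code with the
# package implementation).

# Disability severity for one 6-response pattern: "no difficulty on any
# domain, or some difficulty on only one" -> none; "some difficulty for
# between two and four domains" -> mild; "some difficulty for five or six
# domains, or a lot of difficulty or cannot do at all for at least one" ->
# moderate.
oracle_disability <- function(pattern) {
  n_some <- 0L
  for (r in pattern) {
    if (r == "a_lot_of_difficulty" || r == "cannot_do_at_all") return("moderate")
    if (r == "some_difficulty") n_some <- n_some + 1L
  }
  if (n_some >= 5L) return("moderate")
  if (n_some >= 2L) return("mild")
  "none"
}

# Domain category for one pattern: included when at least k indicators are
# included and the others are not classified below in between; excluded when
# at least k are excluded and the others not above in between; all else in
# between.
oracle_domain <- function(categories, k) {
  n_included <- sum(categories == "included")
  n_excluded <- sum(categories == "excluded")
  rest_min_ok <- all(categories[categories != "included"] != "excluded")
  rest_max_ok <- all(categories[categories != "excluded"] != "included")
  if (n_included >= k && rest_min_ok) return("included")
  if (n_excluded >= k && rest_max_ok) return("excluded")
  "in_between"
}

# Long-run iterative proportional fitting on a count table, run far past
# practical convergence.
oracle_ipf <- function(counts, row_targets, col_targets, iterations = 10000L) {
  x <- counts
  for (i in seq_len(iterations)) {
    x <- x * row_targets / rowSums(x)
    x <- t(t(x) * col_targets / colSums(x))
  }
  x
}

# All 3^n category patterns as a character matrix.
all_category_patterns <- function(n) {
  grid <- expand.grid(rep(list(inclusion_categories), n),
                      stringsAsFactors = FALSE)
  as.matrix(grid)
}

# Draw a random weighted group x category micro-sample for test tables.
random_micro <- function(n, n_groups = 2L, weighted = TRUE) {
  list(categories = sample(inclusion_categories, n, replace = TRUE),
       weights = if (weighted) stats::runif(n, 0.5, 3) else rep(1, n),
       groups = sample(paste0("g", seq_len(n_groups)), n, replace = TRUE))
}
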