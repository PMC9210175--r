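# Dual cut-off k-of-n aggregation of indicator categories to domain categories.

#' Domain aggregation rules
#'
#' Each domain aggregates its `n` indicator categories with a dual cut-off
#' rule: the domain is `included` when at least `k` indicators are `included`
#' and none of the remainder is `excluded`; `excluded` when at least `k` are
#' `excluded` and none of the remainder is `included`; `in_between` otherwise.
#' For a single-indicator domain the category passes through unchanged.
#'
#' The `k` thresholds are stored per domain size rather than derived from a
#' formula — the sequence (n = 1, 2, 3, 4, 12 -> k = 1, 1, 2, 3, 8) fits no
#' clean closed form and is configuration by design.
#'
#' @param domain_id domain the rule applies to.
#' @param n_indicators number of indicators the domain carries.
#' @param k_table named integer vector mapping domain size to threshold;
#'   default `c("1" = 1, "2" = 1, "3" = 2, "4" = 3, "12" = 8)`.
#' @return A list of rules (`domain_id`, `n_indicators`, `k_threshold`) when
#'   called through [default_domain_rules()], or a single rule from
#'   [domain_rule()].
#' @export
domain_rule <- function(domain_id, n_indicators,
                        k_table = c("1" = 1L, "2" = 1L, "3" = 2L,
                                    "4" = 3L, "12" = 8L)) {
  key <- as.character(n_indicators)
  if (!key %in% names(k_table))
    stop("no k threshold configured for a domain of ", n_indicators,
         " indicators", call. = FALSE)
  structure(list(domain_id = domain_id,
                 n_indicators = as.integer(n_indicators),
                 k_threshold = as.integer(k_table[[key]])),
            class = "domain_rule")
}

#' @rdname domain_rule
#' @param domains named integer vector of per-domain indicator counts;
#'   default [inclusion_domains].
#' @export
default_domain_rules <- function(domains = inclusion_domains,
                                 k_table = c("1" = 1L, "2" = 1L, "3" = 2L,
                                             "4" = 3L, "12" = 8L)) {
  rules <- mapply(domain_rule, names(domains), domains,
                  MoreArgs = list(k_table = k_table), SIMPLIFY = FALSE)
  names(rules) <- names(domains)
  rules
}

#' Aggregate one domain's indicator categories
#'
#' @param categories vector (or factor) of inclusion categories, length
#'   `rule$n_indicators`.
#' @param rule a [domain_rule()].
#' @return A length-1 ordered inclusion factor.
#' @examples
#' r4 <- domain_rule("social_relationships", 4)
#' aggregate_domain(c("included", "included", "included", "in_between"), r4)
#' aggregate_domain(c("included", "included", "included", "excluded"), r4)
#' @export
aggregate_domain <- function(categories, rule) {
  stopifnot(inherits(rule, "domain_rule"))
  x <- match(as.character(categories), inclusion_categories)
  if (length(x) != rule$n_indicators)
    stop("domain '", rule$domain_id, "' expects ", rule$n_indicators,
         " categories, got ", length(x), call. = FALSE)
  if (anyNA(x)) return(inclusion_factor(NA))
  n_inc <- sum(x == 3L)
  n_exc <- sum(x == 1L)
  k <- rule$k_threshold
  out <- if (n_inc >= k && n_exc == 0L) "included"
         else if (n_exc >= k && n_inc == 0L) "excluded"
         else "in_between"
  inclusion_factor(out)
}

#' Aggregate the full indicator matrix to domain categories
#'
#' Applies each domain's rule to every respondent. A respondent with any
#' item-missing indicator inside a domain gets `NA` for that domain (excluded
#' from the domain's denominators); per-domain missing counts are attached as
#' attribute `"n_missing"`.
#'
#' @param matrix output of [build_indicator_matrix()].
#' @param configs the indicator configuration set used to build it.
#' @param rules named list of [domain_rule()]s; default
#'   [default_domain_rules()] sized from `configs`.
#' @return A data frame with one ordered-factor column per domain.
#' @export
aggregate_domains <- function(matrix, configs = default_indicator_configs(),
                              rules = NULL) {
  dom <- vapply(configs, `[[`, character(1L), "domain_id")
  if (is.null(rules)) {
    counts <- vapply(split(dom, factor(dom, levels = unique(dom))), length,
                     integer(1L))
    rules <- default_domain_rules(counts)
  }
  code <- vapply(matrix, function(col) match(as.character(col),
                                             inclusion_categories),
                 integer(nrow(matrix)))
  if (nrow(matrix) == 1L) code <- matrix(code, nrow = 1L,
                                         dimnames = list(NULL, names(matrix)))
  out <- lapply(rules, function(rule) {
    cols <- names(configs)[dom == rule$domain_id]
    if (length(cols) != rule$n_indicators)
      stop("rule for '", rule$domain_id, "' expects ", rule$n_indicators,
           " indicators but the configuration carries ", length(cols),
           call. = FALSE)
    sub <- code[, cols, drop = FALSE]
    aggregate_code_matrix(sub, rule$k_threshold)
  })
  res <- as.data.frame(out, optional = TRUE)
  names(res) <- names(rules)
  attr(res, "n_missing") <- vapply(res, function(x) sum(is.na(x)), integer(1L))
  res
}

# vectorised dual cut-off rule on an integer-coded (1/2/3) matrix
aggregate_code_matrix <- function(code, k) {
  miss <- rowSums(is.na(code)) > 0L
  n_inc <- rowSums(code == 3L, na.rm = TRUE)
  n_exc <- rowSums(code == 1L, na.rm = TRUE)
  out <- rep("in_between", nrow(code))
  out[n_inc >= k & n_exc == 0L] <- "included"
  out[n_exc >= k & n_inc == 0L] <- "excluded"
  out[miss] <- NA_character_
  inclusion_factor(out)
}
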