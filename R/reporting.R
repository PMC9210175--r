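# End-to-end pipeline orchestration, gap/pattern summaries, domain
# prioritisation, and table/config I/O.

#' Run the full inclusion-monitoring pipeline
#'
#' Orchestrates every stage: severity classification (respondents with missing
#' functioning or affect responses are dropped and counted, never imputed),
#' indicator scoring, domain aggregation, base weighting and raking, and the
#' three reported comparison families — domains and indicators by disability
#' severity x gender (six groups), and domains by affect severity x gender
#' (four groups) — each with Bonferroni-adjusted p-values. Gender gaps,
#' severity patterns and the three domain prioritisation rankings are derived
#' from the tables.
#'
#' @param records microdata data frame (see [generate_population()] for the
#'   column dictionary), or a [synthetic_scenario()] to generate one.
#' @param configs indicator configuration set.
#' @param margins raking margins ([margin_spec()] list); `NULL` skips raking
#'   (base weights used as-is).
#' @param method chi-squared flavour, see [chisq_test_weighted()].
#' @param alpha significance level for pattern classification (default 0.05).
#' @param m_domains,m_indicators Bonferroni family sizes; default = family
#'   size (9 domains, number of indicators).
#' @param rake_tol,rake_max_iter raking controls, see [rake_weights()].
#' @param seed used only when `records` is a scenario.
#' @return An object of class `inclusion_bundle`: list with elements
#'   `domain_table`, `indicator_table`, `affect_table` (long data frames:
#'   unit, group components, category, weighted_pct, raw_p, adjusted_p),
#'   `gaps`, `patterns`, `rankings`, `weights`, and `log` (drop counts, raking
#'   metadata, seed).
#' @export
run_pipeline <- function(records, configs = default_indicator_configs(),
                         margins = default_margins(),
                         method = c("pearson_effective_n", "rao_scott"),
                         alpha = 0.05,
                         m_domains = NULL, m_indicators = NULL,
                         rake_tol = 1e-8, rake_max_iter = 100L,
                         seed = NULL) {
  method <- match.arg(method)
  if (inherits(records, "synthetic_scenario"))
    records <- generate_population(records, configs,
                                   seed = if (is.null(seed)) records$seed else seed)
  n_input <- nrow(records)

  wg_cols <- paste0("wg_", wg_functioning_domains)
  disability <- classify_disability_severity(records[, wg_cols], on_missing = "na")
  affect <- classify_affect_severity(records$anx_frequency, records$anx_intensity,
                                     records$dep_frequency, records$dep_intensity,
                                     on_missing = "na")
  keep <- !is.na(disability) & !is.na(affect)
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  disability <- disability[keep]
  affect <- factor(as.character(affect[keep]), levels = c("none", "moderate"),
                   ordered = TRUE)

  matrix_ <- build_indicator_matrix(records, configs)
  domains <- aggregate_domains(matrix_, configs)

  w <- base_weights(records$selection_prob)
  rake_meta <- NULL
  if (!is.null(margins)) {
    lv <- records[, vapply(margins, `[[`, character(1L), "dimension"),
                  drop = FALSE]
    w <- rake_weights(w, lv, margins, tol = rake_tol, max_iter = rake_max_iter)
    rake_meta <- attributes(w)
  }

  g6 <- interaction(disability, records$gender, sep = ":", lex.order = TRUE)
  g4 <- interaction(affect, records$gender, sep = ":", lex.order = TRUE)

  m_dom <- if (is.null(m_domains)) ncol(domains) else m_domains
  m_ind <- if (is.null(m_indicators)) ncol(matrix_) else m_indicators
  fam_dom <- run_family(domains, w, g6, method = method, m = m_dom)
  fam_ind <- run_family(matrix_, w, g6, method = method, m = m_ind)
  fam_aff <- run_family(domains, w, g4, method = method, m = m_dom)

  domain_table <- family_long_table(domains, w, g6, fam_dom)
  indicator_table <- family_long_table(matrix_, w, g6, fam_ind)
  affect_table <- family_long_table(domains, w, g4, fam_aff)

  gaps <- rbind(compute_gaps(domain_table, metric = "inclusion_pct"),
                compute_gaps(indicator_table, metric = "exclusion_pct"))
  patterns <- indicator_patterns(matrix_, w, disability, fam_ind, alpha = alpha)
  rankings <- list(
    closest_to_inclusion = prioritise_domains(domain_table, "closest_to_inclusion"),
    farthest_from_inclusion = prioritise_domains(domain_table, "farthest_from_inclusion"),
    largest_disability_gap = prioritise_domains(domain_table, "largest_disability_gap")
  )

  structure(list(
    domain_table = domain_table, indicator_table = indicator_table,
    affect_table = affect_table, gaps = gaps, patterns = patterns,
    rankings = rankings, weights = w,
    families = list(domains = fam_dom, indicators = fam_ind, affect = fam_aff),
    log = list(n_input = n_input, n_dropped_severity = n_dropped,
               n_analysed = nrow(records),
               indicator_missing = attr(matrix_, "n_missing"),
               domain_missing = attr(domains, "n_missing"),
               raking = rake_meta, seed = seed, method = method,
               alpha = alpha, m_domains = m_dom, m_indicators = m_ind)
  ), class = "inclusion_bundle")
}

# long-format table: unit x group x category weighted percentages + p-values
family_long_table <- function(unit_categories, w, groups, family) {
  pieces <- lapply(names(unit_categories), function(u) {
    wp <- suppressWarnings(weighted_proportions(unit_categories[[u]], w, groups))
    long <- data.frame(
      unit = u,
      group = rep(wp$group, times = length(inclusion_categories)),
      category = rep(inclusion_categories, each = nrow(wp)),
      weighted_pct = unlist(wp[inclusion_categories], use.names = FALSE),
      row.names = NULL
    )
    long$raw_p <- family$summary$raw_p[family$summary$unit == u]
    long$adjusted_p <- family$summary$adjusted_p[family$summary$unit == u]
    long
  })
  out <- do.call(rbind, pieces)
  parts <- strsplit(as.character(out$group), ":", fixed = TRUE)
  out$severity <- vapply(parts, `[[`, character(1L), 1L)
  out$gender <- vapply(parts, `[[`, character(1L), 2L)
  out
}

#' @export
print.inclusion_bundle <- function(x, ...) {
  cat("Inclusion monitoring bundle:", x$log$n_analysed, "respondents analysed (",
      x$log$n_dropped_severity, "dropped with undefined severity)\n")
  cat("Tables: domains", length(unique(x$domain_table$unit)), "x",
      length(unique(x$domain_table$group)), "groups; indicators",
      length(unique(x$indicator_table$unit)), "x",
      length(unique(x$indicator_table$group)), "; affect domains",
      length(unique(x$affect_table$unit)), "x",
      length(unique(x$affect_table$group)), "\n")
  invisible(x)
}

#' Gender gaps in inclusion or exclusion
#'
#' For every unit and severity class present in a long table, the male minus
#' female percentage on the chosen category. A positive gap with
#' `metric = "inclusion_pct"` means men are better off on inclusion (a
#' "female inclusion gap"); a positive gap with `metric = "exclusion_pct"`
#' means men are worse off on exclusion (a "male exclusion gap").
#'
#' @param table a long table from [run_pipeline()] (`domain_table`,
#'   `indicator_table` or `affect_table`).
#' @param metric `"inclusion_pct"` (gap on the included share) or
#'   `"exclusion_pct"` (gap on the excluded share).
#' @return Data frame: unit, severity, male, female, gap, worse_off, metric.
#'   Severity classes missing a gender are skipped with a warning.
#' @export
compute_gaps <- function(table, metric = c("inclusion_pct", "exclusion_pct")) {
  metric <- match.arg(metric)
  cat_wanted <- if (metric == "inclusion_pct") "included" else "excluded"
  sub <- table[table$category == cat_wanted, ]
  out <- list()
  for (u in unique(sub$unit)) {
    for (s in unique(sub$severity[sub$unit == u])) {
      rows <- sub[sub$unit == u & sub$severity == s, ]
      male <- rows$weighted_pct[rows$gender == "male"]
      female <- rows$weighted_pct[rows$gender == "female"]
      if (length(male) != 1L || length(female) != 1L) {
        warning("skipping ", u, "/", s, ": missing a gender level",
                call. = FALSE)
        next
      }
      gap <- male - female
      worse <- if (gap == 0) NA_character_
               else if (metric == "inclusion_pct") {
                 if (gap > 0) "female" else "male"
               } else {
                 if (gap > 0) "male" else "female"
               }
      out[[length(out) + 1L]] <- data.frame(
        unit = u, severity = s, male = male, female = female,
        gap = gap, worse_off = worse, metric = metric)
    }
  }
  if (!length(out))
    return(data.frame(unit = character(), severity = character(),
                      male = numeric(), female = numeric(), gap = numeric(),
                      worse_off = character(), metric = character()))
  do.call(rbind, out)
}

#' Classify an indicator's severity pattern
#'
#' Labels how exclusion varies over the three disability-severity classes
#' (gender-pooled, weighted): `no_significant_difference` when the adjusted p
#' is at or above `alpha`; otherwise `monotone_worsening` when exclusion rises
#' strictly none < mild < moderate; `mild_equals_moderate_worse` when mild and
#' moderate are within `band` percentage points of each other and both exceed
#' none; `mild_worst` when mild has the single highest exclusion; `none_worst`
#' when the no-disability class has the highest exclusion.
#'
#' @param exclusion_pct named numeric: exclusion percentage for `none`,
#'   `mild`, `moderate`.
#' @param adjusted_p the indicator's Bonferroni-adjusted p-value (NA counts as
#'   not significant).
#' @param alpha significance level (default 0.05).
#' @param band closeness band in percentage points for
#'   `mild_equals_moderate_worse` (default 2).
#' @return Character pattern label.
#' @export
classify_severity_pattern <- function(exclusion_pct, adjusted_p,
                                      alpha = 0.05, band = 2) {
  need <- disability_severity_levels
  if (!all(need %in% names(exclusion_pct)) || anyNA(exclusion_pct[need]))
    stop("pattern undefined: exclusion percentages required for ",
         paste(need, collapse = ", "), call. = FALSE)
  e <- exclusion_pct[need]
  if (is.na(adjusted_p) || adjusted_p >= alpha) return("no_significant_difference")
  if (abs(e["mild"] - e["moderate"]) <= band &&
      e["mild"] > e["none"] && e["moderate"] > e["none"])
    return("mild_equals_moderate_worse")
  if (e["none"] < e["mild"] && e["mild"] < e["moderate"])
    return("monotone_worsening")
  if (e["mild"] >= e["none"] && e["mild"] >= e["moderate"]) return("mild_worst")
  if (e["none"] >= e["mild"] && e["none"] >= e["moderate"]) return("none_worst")
  # residual: moderate worst but none >= mild
  "mild_equals_moderate_worse"
}

# per-indicator severity patterns from micro data (gender-pooled exclusion)
indicator_patterns <- function(matrix_, w, disability, family, alpha = 0.05,
                               band = 2) {
  out <- lapply(names(matrix_), function(u) {
    wp <- suppressWarnings(weighted_proportions(matrix_[[u]], w, disability))
    excl <- stats::setNames(wp$excluded, wp$group)
    p <- family$summary$adjusted_p[family$summary$unit == u]
    label <- tryCatch(
      classify_severity_pattern(excl, p, alpha = alpha, band = band),
      error = function(e) NA_character_)
    data.frame(indicator = u, pattern = label, adjusted_p = p,
               excl_none = excl[["none"]], excl_mild = excl[["mild"]],
               excl_moderate = excl[["moderate"]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank domains for policy prioritisation
#'
#' Three targeting approaches over a domain table, computed on the chosen
#' population:
#' \describe{
#'   \item{closest_to_inclusion}{among domains whose inclusion is below
#'     `ceiling`, rank by inclusion percentage descending, preferring large
#'     in-between mass on ties — target the domains easiest to lift over the
#'     cut-off.}
#'   \item{farthest_from_inclusion}{rank by inclusion ascending (or, with
#'     `by_exclusion = TRUE`, by exclusion descending) — target the worst-off
#'     domains.}
#'   \item{largest_disability_gap}{rank by inclusion(no disability) minus
#'     inclusion(with disability, mild and moderate pooled by weight)
#'     descending — target the disability-and-development gap.}
#' }
#' Remaining ties break alphabetically by domain id and are flagged.
#'
#' @param domain_table long domain table from [run_pipeline()].
#' @param approach one of the three approaches above.
#' @param population severity classes pooled for the first two approaches
#'   (default: the with-disability classes, mild + moderate).
#' @param ceiling inclusion ceiling for `closest_to_inclusion` (default 80).
#' @param by_exclusion variant flag for `farthest_from_inclusion`.
#' @param weights_by_group optional named numeric: pooling weight for each
#'   severity:gender group (e.g. the groups' weighted population shares).
#'   Equal pooling weights are used when omitted, since the percentage table
#'   alone does not carry the group sizes.
#' @return Data frame of class `priority_ranking`: domain, score, rank, tied.
#' @export
prioritise_domains <- function(domain_table,
                               approach = c("closest_to_inclusion",
                                            "farthest_from_inclusion",
                                            "largest_disability_gap"),
                               population = c("mild", "moderate"),
                               ceiling = 80, by_exclusion = FALSE,
                               weights_by_group = NULL) {
  approach <- match.arg(approach)
  pooled <- pool_domain_table(domain_table, weights_by_group)
  units <- sort(unique(pooled$unit))

  score_of <- function(unit) {
    rows <- pooled[pooled$unit == unit, ]
    inc <- stats::weighted.mean(
      rows$weighted_pct[rows$category == "included" &
                          rows$severity %in% population],
      rows$pool_w[rows$category == "included" & rows$severity %in% population])
    inb <- stats::weighted.mean(
      rows$weighted_pct[rows$category == "in_between" &
                          rows$severity %in% population],
      rows$pool_w[rows$category == "in_between" & rows$severity %in% population])
    exc <- stats::weighted.mean(
      rows$weighted_pct[rows$category == "excluded" &
                          rows$severity %in% population],
      rows$pool_w[rows$category == "excluded" & rows$severity %in% population])
    inc_none <- stats::weighted.mean(
      rows$weighted_pct[rows$category == "included" & rows$severity == "none"],
      rows$pool_w[rows$category == "included" & rows$severity == "none"])
    c(inclusion = inc, in_between = inb, exclusion = exc,
      gap = inc_none - inc)
  }
  scores <- t(vapply(units, score_of, numeric(4L)))

  df <- switch(approach,
    closest_to_inclusion = {
      keep <- scores[, "inclusion"] < ceiling
      d <- data.frame(domain = units[keep],
                      score = scores[keep, "inclusion"],
                      in_between = scores[keep, "in_between"])
      d[order(-d$score, -d$in_between, d$domain), ]
    },
    farthest_from_inclusion = {
      if (by_exclusion) {
        d <- data.frame(domain = units, score = scores[, "exclusion"])
        d[order(-d$score, d$domain), ]
      } else {
        d <- data.frame(domain = units, score = scores[, "inclusion"])
        d[order(d$score, d$domain), ]
      }
    },
    largest_disability_gap = {
      d <- data.frame(domain = units, score = scores[, "gap"])
      d[order(-d$score, d$domain), ]
    })
  df$rank <- seq_len(nrow(df))
  df$tied <- duplicated(df$score) | duplicated(df$score, fromLast = TRUE)
  rownames(df) <- NULL
  attr(df, "approach") <- approach
  class(df) <- c("priority_ranking", "data.frame")
  df
}

# pooled (per-severity, gender-combined) percentages; pooling weights default
# equal across the gender cells of a severity class
pool_domain_table <- function(domain_table, weights_by_group = NULL) {
  tab <- domain_table
  tab$pool_w <- if (is.null(weights_by_group)) 1
                else weights_by_group[as.character(tab$group)]
  agg <- stats::aggregate(
    cbind(weighted_pct = tab$weighted_pct * tab$pool_w, pool_w = tab$pool_w),
    by = list(unit = tab$unit, severity = tab$severity, category = tab$category),
    FUN = sum)
  agg$weighted_pct <- agg$weighted_pct / agg$pool_w
  agg
}

#' Write a result bundle to disk
#'
#' Emits the three long tables, the gap, pattern and ranking summaries as CSV,
#' and a JSON run-metadata file (drop counts, raking metadata, seed, settings).
#'
#' @param bundle an `inclusion_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "inclusion_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    domain_table = file.path(dir, "domain_table.csv"),
    indicator_table = file.path(dir, "indicator_table.csv"),
    affect_table = file.path(dir, "affect_table.csv"),
    gaps = file.path(dir, "gaps.csv"),
    patterns = file.path(dir, "patterns.csv")
  )
  for (nm in names(paths))
    utils::write.csv(bundle[[nm]], paths[nm], row.names = FALSE)
  rk <- do.call(rbind, lapply(names(bundle$rankings), function(a) {
    d <- bundle$rankings[[a]]
    data.frame(approach = a, d[, c("domain", "score", "rank", "tied")])
  }))
  rk_path <- file.path(dir, "rankings.csv")
  utils::write.csv(rk, rk_path, row.names = FALSE)
  meta <- bundle$log
  meta$raking <- meta$raking[c("iterations", "max_margin_error", "converged")]
  meta_path <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, rankings = rk_path, metadata = meta_path))
}

#' Read microdata from CSV
#'
#' One row per respondent, UTF-8, header row required; see
#' [generate_population()] for the column dictionary.
#'
#' @param path CSV file path.
#' @export
read_microdata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Type-I-error simulation for a comparison family under the null
#'
#' Repeatedly redraws indicator responses under a null scenario (identical
#' category probabilities across groups), aggregates to domains, runs the
#' family of tests over the severity x gender groups, and records whether any
#' Bonferroni-adjusted p-value falls below `alpha`. The design, group labels
#' and weights are generated once and held fixed; only the outcome draws vary,
#' which is exactly the null hypothesis of the homogeneity tests.
#'
#' @param scenario base scenario; [null_scenario()] is applied to it.
#' @param n_replicates number of Monte Carlo replicates.
#' @param alpha family-wise significance level.
#' @param method chi-squared flavour.
#' @param seed RNG seed.
#' @param unit `"domains"` (default) or `"indicators"`: which family to test.
#' @return List: `rejection_rate` (family-wise), `unit_rates` (per-unit
#'   rejection rates), `n_replicates`, `alpha`, `rejections` (logical vector).
#' @export
simulate_type1 <- function(scenario, n_replicates = 500L, alpha = 0.05,
                           method = "pearson_effective_n", seed = 1L,
                           unit = c("domains", "indicators")) {
  simulate_rejections(null_scenario(scenario), n_replicates = n_replicates,
                      alpha = alpha, method = method, seed = seed,
                      unit = unit)
}

#' Rejection-rate simulation for a comparison family
#'
#' The engine behind [simulate_type1()], also usable for power: redraws the
#' indicator responses of a fixed synthetic population under `scenario`'s
#' (possibly effect-carrying) probabilities, runs the family of comparisons
#' each time, and records the Bonferroni-adjusted rejections per unit and
#' family-wise. Under a [null_scenario()] the family-wise rate estimates the
#' type-I error; with an effect planted via `indicator_prob_overrides` the
#' affected unit's rate estimates power.
#'
#' @inheritParams simulate_type1
#' @export
simulate_rejections <- function(scenario, n_replicates = 500L, alpha = 0.05,
                                method = "pearson_effective_n", seed = 1L,
                                unit = c("domains", "indicators")) {
  unit <- match.arg(unit)
  configs <- default_indicator_configs()
  set.seed(seed)
  pop <- generate_population(scenario, configs, seed = sample.int(2^31 - 1L, 1L))
  wg_cols <- paste0("wg_", wg_functioning_domains)
  disability <- classify_disability_severity(pop[, wg_cols])
  groups <- interaction(disability, pop$gender, sep = ":", lex.order = TRUE)
  w <- base_weights(pop$selection_prob)
  g <- match(as.character(disability), disability_severity_levels)
  hits <- vapply(seq_len(n_replicates), function(r) {
    ind <- draw_indicator_responses(scenario, configs, g)
    mat <- build_indicator_matrix(ind, configs)
    cats <- if (unit == "domains") aggregate_domains(mat, configs) else mat
    fam <- run_family(cats, w, groups, method = method)
    rej <- fam$summary$adjusted_p < alpha
    rej[is.na(rej)] <- FALSE
    stats::setNames(rej, fam$summary$unit)
  }, logical(if (unit == "domains") length(inclusion_domains)
             else length(configs)))
  rejections <- apply(hits, 2L, any)
  list(rejection_rate = mean(rejections),
       unit_rates = rowMeans(hits),
       n_replicates = n_replicates, alpha = alpha, rejections = rejections)
}
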