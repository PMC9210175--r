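# JSON round-trip for the pipeline configuration: indicator maps, domain
# thresholds, severity cut-offs, affect grid, raking margins and analysis
# settings.

#' Read and write the pipeline configuration
#'
#' The configuration file is JSON with (all optional, defaults applied):
#' `indicators` (per-indicator id, domain, mode, response_map, refusal_codes,
#' missing_codes), `k_table` (domain-size -> k threshold), `severity_cutoffs`
#' (`variant`, `none_max_some`, `mild_max_some`), `affect_grid` (frequency x
#' intensity -> composite level), `margins` (dimension -> level shares),
#' `rake_tol`, `rake_max_iter`, `method`, `alpha`, `m_domains`,
#' `m_indicators`, `seed`, and `scenario` (any [synthetic_scenario()]
#' argument; matrices as row-major nested lists with names).
#'
#' @param path JSON file path.
#' @return For `read_pipeline_config()`: a list with fully constructed
#'   components (`configs`, `k_table`, `cutoffs`, `affect_grid`, `margins`,
#'   `settings`, `scenario`). `write_pipeline_config()` writes the default
#'   configuration (or the one supplied) and returns the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  configs <- if (is.null(raw$indicators)) default_indicator_configs() else {
    out <- lapply(raw$indicators, function(x)
      indicator_config(x$indicator_id, x$domain_id, x$mode,
                       unlist(x$response_map),
                       refusal_codes = unlist(x$refusal_codes %||% "refused"),
                       missing_codes = unlist(x$missing_codes %||% character())))
    names(out) <- vapply(out, `[[`, character(1L), "indicator_id")
    out
  }
  k_table <- if (is.null(raw$k_table))
    c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 3L, "12" = 8L)
  else vapply(raw$k_table, as.integer, integer(1L))
  cutoffs <- if (is.null(raw$severity_cutoffs)) severity_cutoffs() else
    do.call(severity_cutoffs, lapply(raw$severity_cutoffs, unlist))
  grid <- if (is.null(raw$affect_grid)) default_affect_grid() else {
    g <- default_affect_grid()
    for (f in names(raw$affect_grid))
      for (i in names(raw$affect_grid[[f]]))
        g[f, i] <- raw$affect_grid[[f]][[i]]
    validate_affect_grid(g)
  }
  margins <- if (is.null(raw$margins)) default_margins() else
    lapply(names(raw$margins), function(d)
      margin_spec(d, unlist(raw$margins[[d]])))
  scenario <- if (is.null(raw$scenario)) synthetic_scenario() else {
    args <- lapply(raw$scenario, function(x)
      if (is.list(x) && all(vapply(x, is.list, logical(1L))))
        do.call(rbind, lapply(x, unlist)) else unlist(x))
    do.call(synthetic_scenario, args)
  }
  settings <- list(
    rake_tol = raw$rake_tol %||% 1e-8,
    rake_max_iter = as.integer(raw$rake_max_iter %||% 100L),
    method = raw$method %||% "pearson_effective_n",
    alpha = raw$alpha %||% 0.05,
    m_domains = raw$m_domains, m_indicators = raw$m_indicators,
    seed = as.integer(raw$seed %||% 1L)
  )
  list(configs = configs, k_table = k_table, cutoffs = cutoffs,
       affect_grid = grid, margins = margins, settings = settings,
       scenario = scenario)
}

#' @rdname read_pipeline_config
#' @param configs indicator configuration set to serialise.
#' @export
write_pipeline_config <- function(path, configs = default_indicator_configs()) {
  payload <- list(
    indicators = lapply(unname(configs), function(cf)
      list(indicator_id = cf$indicator_id, domain_id = cf$domain_id,
           mode = cf$mode, response_map = as.list(cf$response_map),
           refusal_codes = cf$refusal_codes, missing_codes = cf$missing_codes)),
    k_table = as.list(c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 3L, "12" = 8L)),
    rake_tol = 1e-8, rake_max_iter = 100L,
    method = "pearson_effective_n", alpha = 0.05, seed = 1L
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
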