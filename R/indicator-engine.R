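# Indicator scoring: raw response codes -> the ordered inclusion trichotomy,
# driven by a declarative per-indicator configuration.

#' Inclusion categories
#'
#' The ordered trichotomy used at both the indicator and domain level:
#' `excluded < in_between < included`.
#' @export
inclusion_categories <- c("excluded", "in_between", "included")

#' Make an inclusion-category factor
#'
#' @param x character vector of category names (or an existing factor).
#' @return An ordered factor `excluded < in_between < included`.
#' @export
inclusion_factor <- function(x) {
  factor(as.character(x), levels = inclusion_categories, ordered = TRUE)
}

#' Construct a per-indicator scoring configuration
#'
#' An indicator configuration maps every admissible raw response code of one
#' survey item to an inclusion category. `binary` indicators map every
#' substantive code to `included` or `excluded` only (`in_between` then arises
#' solely from refusals); `nuanced` indicators map at least one substantive
#' code to `in_between`. Refusal codes always map to `in_between`, in either
#' mode. Item-missing codes are kept separate from refusals: a respondent with
#' a missing code is dropped from that indicator's denominators rather than
#' scored.
#'
#' @param indicator_id short name of the indicator.
#' @param domain_id domain the indicator belongs to.
#' @param mode `"binary"` or `"nuanced"`.
#' @param response_map named character vector: names are response codes,
#'   values are inclusion categories.
#' @param refusal_codes codes scored `in_between` regardless of mode.
#' @param missing_codes codes treated as item-missing (respondent excluded
#'   from this indicator's denominators).
#' @return An object of class `indicator_config`.
#' @export
indicator_config <- function(indicator_id, domain_id,
                             mode = c("binary", "nuanced"),
                             response_map,
                             refusal_codes = "refused",
                             missing_codes = character()) {
  mode <- match.arg(mode)
  if (is.null(names(response_map)) || any(!nzchar(names(response_map))))
    stop("response_map must be a fully named vector (code -> category)", call. = FALSE)
  if (!all(response_map %in% inclusion_categories))
    stop("response_map values must be inclusion categories", call. = FALSE)
  substantive <- response_map[!names(response_map) %in% refusal_codes]
  if (mode == "binary" && any(substantive == "in_between"))
    stop("binary indicator '", indicator_id,
         "' maps a substantive code to in_between", call. = FALSE)
  if (mode == "nuanced" && !any(substantive == "in_between"))
    stop("nuanced indicator '", indicator_id,
         "' must map at least one substantive code to in_between", call. = FALSE)
  if (any(refusal_codes %in% names(substantive)))
    stop("refusal codes overlap substantive codes for '", indicator_id, "'",
         call. = FALSE)
  structure(list(indicator_id = indicator_id, domain_id = domain_id,
                 mode = mode, response_map = response_map,
                 refusal_codes = refusal_codes, missing_codes = missing_codes),
            class = "indicator_config")
}

#' The nine inclusion domains and their indicator counts
#'
#' Domain identifiers in reporting order, with the number of indicators each
#' carries in the default configuration (4, 12, 2, 2, 2, 2, 3, 1, 4).
#' @export
inclusion_domains <- c(
  social_relationships = 4L,
  living_conditions = 12L,
  economic_opportunities = 2L,
  support_systems = 2L,
  institutional_status = 2L,
  voice = 2L,
  education = 3L,
  healthcare_access = 1L,
  personal_safety = 4L
)

# (indicator_id, domain, mode) table for the default instrument. The
# indicator-level cut-off definitions of the source instrument are not
# published; these maps are reconstructions from the indicator names and are
# configuration, not code - replace them to match any instrument.
default_indicator_table <- function() {
  tab <- rbind(
    c("unpaid_work_humiliation",   "social_relationships",  "binary"),
    c("unpaid_work_value",         "social_relationships",  "binary"),
    c("reciprocate_support",       "social_relationships",  "binary"),
    c("community_event_inclusion", "social_relationships",  "nuanced"),
    c("food_security",             "living_conditions",     "nuanced"),
    c("drinking_water",            "living_conditions",     "nuanced"),
    c("domestic_water",            "living_conditions",     "nuanced"),
    c("cooking_energy",            "living_conditions",     "nuanced"),
    c("lighting_energy",           "living_conditions",     "nuanced"),
    c("heating_energy",            "living_conditions",     "nuanced"),
    c("home_toilet",               "living_conditions",     "nuanced"),
    c("toilet_modifications",      "living_conditions",     "binary"),
    c("clothing_ownership",        "living_conditions",     "binary"),
    c("clothing_quality",          "living_conditions",     "nuanced"),
    c("bedding_ownership",         "living_conditions",     "binary"),
    c("eviction_concern",          "living_conditions",     "binary"),
    c("labour_force_status",       "economic_opportunities", "nuanced"),
    c("public_transport",          "economic_opportunities", "nuanced"),
    c("support_availability",      "support_systems",       "binary"),
    c("grant_receipt",             "support_systems",       "binary"),
    c("identity_document",         "institutional_status",  "binary"),
    c("birth_certificate",         "institutional_status",  "binary"),
    c("local_decision_making",     "voice",                 "nuanced"),
    c("voting_inclusion",          "voice",                 "binary"),
    c("schooling",                 "education",             "nuanced"),
    c("basic_literacy",            "education",             "nuanced"),
    c("basic_numeracy",            "education",             "nuanced"),
    c("healthcare_access_quality", "healthcare_access",     "nuanced"),
    c("fuel_collection_hazards",   "personal_safety",       "binary"),
    c("water_collection_hazards",  "personal_safety",       "binary"),
    c("safety_at_home",            "personal_safety",       "nuanced"),
    c("safety_neighbourhood",      "personal_safety",       "nuanced")
  )
  data.frame(indicator_id = tab[, 1L], domain_id = tab[, 2L], mode = tab[, 3L],
             stringsAsFactors = FALSE)
}

#' Default indicator configuration: 32 indicators over nine domains
#'
#' Ships the full instrument configuration: 14 binary and 18 nuanced
#' indicators partitioned over the nine domains of [inclusion_domains]. Binary
#' indicators use codes `"included"`/`"excluded"`-valued pairs such as
#' `has`/`lacks`; nuanced indicators add a substantive middle code. The
#' food-security indicator, for example, maps `food_secure -> included`,
#' `mild_moderate_food_insecurity -> in_between`,
#' `severe_food_insecurity -> excluded`. The code `"refused"` is a refusal on
#' every indicator and `"missing"` an item-missing.
#'
#' The underlying instrument's exact cut-off definitions are not published;
#' these maps are plausible reconstructions and are meant to be replaced (via
#' [indicator_config()] or a JSON config, see [read_pipeline_config()]) to
#' match a real instrument.
#'
#' @return A named list of [indicator_config()] objects, one per indicator.
#' @export
default_indicator_configs <- function() {
  tab <- default_indicator_table()
  special <- list(
    food_security = c(food_secure = "included",
                      mild_moderate_food_insecurity = "in_between",
                      severe_food_insecurity = "excluded")
  )
  configs <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$indicator_id[i]
    mode <- tab$mode[i]
    map <- if (!is.null(special[[id]])) {
      special[[id]]
    } else if (mode == "binary") {
      c(adequate = "included", inadequate = "excluded")
    } else {
      c(adequate = "included", partial = "in_between", inadequate = "excluded")
    }
    indicator_config(id, tab$domain_id[i], mode, map,
                     refusal_codes = "refused", missing_codes = "missing")
  })
  names(configs) <- tab$indicator_id
  validate_indicator_configs(configs)
  configs
}

#' Validate a full indicator configuration set
#'
#' Checks the structural invariants the aggregation stage relies on: every
#' entry is an [indicator_config()]; indicator ids are unique; every indicator
#' belongs to exactly one known domain; each domain carries exactly the number
#' of indicators declared in `domains`.
#'
#' @param configs named list of [indicator_config()] objects.
#' @param domains named integer vector of expected per-domain indicator
#'   counts; default [inclusion_domains].
#' @return `configs`, invisibly; stops on violation.
#' @export
validate_indicator_configs <- function(configs, domains = inclusion_domains) {
  stopifnot(all(vapply(configs, inherits, logical(1L), "indicator_config")))
  ids <- vapply(configs, `[[`, character(1L), "indicator_id")
  if (anyDuplicated(ids)) stop("duplicate indicator ids", call. = FALSE)
  if (!identical(names(configs), unname(ids)))
    stop("configs must be named by indicator_id", call. = FALSE)
  dom <- vapply(configs, `[[`, character(1L), "domain_id")
  if (!all(dom %in% names(domains)))
    stop("unknown domain id: ", paste(setdiff(dom, names(domains)), collapse = ", "),
         call. = FALSE)
  counts <- table(factor(dom, levels = names(domains)))
  if (!all(counts == domains))
    stop("per-domain indicator counts do not match the configured layout",
         call. = FALSE)
  invisible(configs)
}

#' Score one indicator's raw responses
#'
#' Pure lookup: refusal codes score `in_between` regardless of mode,
#' substantive codes score their mapped category, item-missing codes score
#' `NA` (excluded from denominators downstream). Any other code is a
#' configuration error naming the indicator and offending code.
#'
#' @param response character vector of raw response codes.
#' @param config an [indicator_config()].
#' @return Ordered factor of inclusion categories, `NA` for item-missing.
#' @export
classify_indicator <- function(response, config) {
  stopifnot(inherits(config, "indicator_config"))
  response <- as.character(response)
  out <- rep(NA_character_, length(response))
  refusal <- response %in% config$refusal_codes
  out[refusal] <- "in_between"
  mapped <- match(response, names(config$response_map))
  sub <- !refusal & !is.na(mapped)
  out[sub] <- unname(config$response_map[mapped[sub]])
  unknown <- !refusal & is.na(mapped) & !response %in% config$missing_codes &
    !is.na(response)
  if (any(unknown))
    stop("unmapped response code '", response[which(unknown)[1L]],
         "' for indicator '", config$indicator_id, "'", call. = FALSE)
  inclusion_factor(out)
}

#' Build the respondent-by-indicator inclusion matrix
#'
#' Scores every configured indicator for every record. Cells are inclusion
#' categories; item-missing responses yield `NA` cells (those respondents are
#' excluded from the affected indicator's denominators downstream) and
#' per-indicator missing counts are attached as attribute `"n_missing"`.
#'
#' @param records data frame with one column per indicator, named
#'   `ind_<indicator_id>` (or bare `<indicator_id>`).
#' @param configs named list of [indicator_config()] objects covering the
#'   instrument; default [default_indicator_configs()].
#' @return A data frame of ordered factors, one column per indicator, with
#'   attribute `"n_missing"` (named integer vector).
#' @export
build_indicator_matrix <- function(records, configs = default_indicator_configs()) {
  validate_indicator_configs(configs,
                             domains = table_to_counts(configs))
  cols <- lapply(configs, function(cf) {
    col <- paste0("ind_", cf$indicator_id)
    if (!col %in% names(records)) col <- cf$indicator_id
    if (!col %in% names(records))
      stop("records lack a column for indicator '", cf$indicator_id, "'",
           call. = FALSE)
    classify_indicator(records[[col]], cf)
  })
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- names(configs)
  attr(out, "n_missing") <- vapply(out, function(x) sum(is.na(x)), integer(1L))
  out
}

# derive the per-domain counts actually present in a config set, so
# build_indicator_matrix also accepts reduced instruments in tests
table_to_counts <- function(configs) {
  dom <- vapply(configs, `[[`, character(1L), "domain_id")
  counts <- table(dom)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
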