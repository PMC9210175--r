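# Synthetic survey microdata with the structure the analysis pipeline
# assumes: stratified two-stage design, severity prevalences, severity-skewed
# demographics, group-specific indicator probabilities, small refusal rates.

#' Default raking margins
#'
#' Plausible national adult (16+) population shares for the three raking
#' dimensions — age group, gender, population group — used as calibration
#' defaults for the synthetic scenario and the pipeline. Replace with real
#' census margins for any substantive use.
#'
#' @return A list of three [margin_spec()] objects.
#' @export
default_margins <- function() {
  list(
    margin_spec("age_group", c("16_24" = 0.25, "25_64" = 0.66, "65_plus" = 0.09)),
    margin_spec("gender", c(male = 0.48, female = 0.52)),
    margin_spec("population_group",
                c(black_african = 0.807, coloured = 0.088,
                  indian_asian = 0.025, white = 0.080))
  )
}

#' Define a synthetic-data scenario
#'
#' The generative parameters for [generate_population()]. Defaults are
#' calibrated to the severity prevalences and severity-conditional
#' demographics of a large national disability-inclusion survey
#' (about 80/10/10% none/mild/moderate disability severity, 80/20% none/
#' moderate affect severity, women over-represented at higher severity), so
#' that synthetic outputs are plausibly scaled.
#'
#' @param n number of respondents (default 8499).
#' @param joint_severity 3 x 2 matrix of joint disability (rows: none, mild,
#'   moderate) by affect (columns: none, moderate) severity probabilities;
#'   normalised to sum to 1.
#' @param gender_male_by_severity male share within each disability-severity
#'   class.
#' @param age_by_severity 3 x 3 matrix, rows = severity, columns = age bins
#'   16_24 / 25_64 / 65_plus; rows normalised.
#' @param popgroup_by_severity 3 x 4 matrix, rows = severity, columns =
#'   population groups; rows normalised.
#' @param indicator_probs 3 x 3 matrix of inclusion-category probabilities by
#'   disability-severity group (rows none/mild/moderate; columns
#'   excluded/in_between/included). Applied to every indicator; for binary
#'   indicators the `in_between` mass is reallocated proportionally to the two
#'   extreme categories (binary items have no substantive middle code).
#' @param indicator_prob_overrides named list (indicator_id -> 3 x 3 matrix
#'   like `indicator_probs`) overriding the shared probabilities for specific
#'   indicators, e.g. to plant an effect in a single domain; empty by default.
#' @param refusal_rate probability that any single indicator response is a
#'   refusal (default 0.005).
#' @param latent_rho within-respondent correlation of indicator outcomes via
#'   a shared latent propensity (Gaussian copula); 0 (default) draws
#'   indicators independently given group.
#' @param provinces,eas_per_stratum design structure: `provinces` x 2
#'   (urban/rural) strata, each with `eas_per_stratum` enumeration areas.
#' @param ea_prob,dwelling_prob named numeric (urban, rural) stage-selection
#'   probabilities; a respondent's dwelling selection probability is their
#'   product, so urban and rural respondents carry different base weights.
#'   Set both stages equal across strata for a self-weighting design.
#' @param seed integer random seed fixing the full output stream.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    n = 8499L,
    joint_severity = matrix(c(0.666, 0.068, 0.068, 0.137, 0.027, 0.035),
                            nrow = 3L,
                            dimnames = list(disability_severity_levels,
                                            c("none", "moderate"))),
    gender_male_by_severity = c(none = 0.497, mild = 0.347, moderate = 0.306),
    age_by_severity = matrix(c(0.290, 0.109, 0.088,
                               0.661, 0.562, 0.584,
                               0.049, 0.329, 0.328),
                             nrow = 3L,
                             dimnames = list(disability_severity_levels,
                                             c("16_24", "25_64", "65_plus"))),
    popgroup_by_severity = matrix(c(0.774, 0.800, 0.803,
                                    0.089, 0.101, 0.109,
                                    0.027, 0.039, 0.032,
                                    0.110, 0.060, 0.056),
                                  nrow = 3L,
                                  dimnames = list(disability_severity_levels,
                                                  c("black_african", "coloured",
                                                    "indian_asian", "white"))),
    indicator_probs = matrix(c(0.15, 0.25, 0.30,
                               0.15, 0.20, 0.20,
                               0.70, 0.55, 0.50),
                             nrow = 3L,
                             dimnames = list(disability_severity_levels,
                                             inclusion_categories)),
    indicator_prob_overrides = list(),
    refusal_rate = 0.005,
    latent_rho = 0,
    provinces = 9L,
    eas_per_stratum = 4L,
    ea_prob = c(urban = 0.10, rural = 0.20),
    dwelling_prob = c(urban = 0.02, rural = 0.05),
    seed = 1L) {
  if (any(joint_severity < 0) || sum(joint_severity) <= 0)
    stop("infeasible joint severity table", call. = FALSE)
  joint_severity <- joint_severity / sum(joint_severity)
  norm_rows <- function(m) m / rowSums(m)
  sc <- list(n = as.integer(n),
             joint_severity = joint_severity,
             gender_male_by_severity = gender_male_by_severity,
             age_by_severity = norm_rows(age_by_severity),
             popgroup_by_severity = norm_rows(popgroup_by_severity),
             indicator_probs = norm_rows(indicator_probs),
             indicator_prob_overrides = lapply(indicator_prob_overrides,
                                               norm_rows),
             refusal_rate = refusal_rate,
             latent_rho = latent_rho,
             provinces = as.integer(provinces),
             eas_per_stratum = as.integer(eas_per_stratum),
             ea_prob = ea_prob, dwelling_prob = dwelling_prob,
             seed = as.integer(seed))
  stopifnot(refusal_rate >= 0, refusal_rate < 1,
            latent_rho >= 0, latent_rho < 1,
            all(sc$indicator_probs >= 0))
  structure(sc, class = "synthetic_scenario")
}

#' Null scenario: no group differences in indicator outcomes
#'
#' Returns the scenario with every disability-severity group's indicator
#' category probabilities set to the no-disability group's values, so all
#' groups share identical generative outcome distributions (the null
#' hypothesis of the group comparisons). Idempotent.
#'
#' @param base a [synthetic_scenario()].
#' @export
null_scenario <- function(base) {
  stopifnot(inherits(base, "synthetic_scenario"))
  flatten <- function(p) {
    p[] <- rep(p["none", ], each = nrow(p))
    p
  }
  base$indicator_probs <- flatten(base$indicator_probs)
  base$indicator_prob_overrides <- lapply(base$indicator_prob_overrides,
                                          flatten)
  base
}

# All 4^6 functioning patterns partitioned by severity class (indices into
# the pattern matrix), computed from the classifier itself so generated
# patterns round-trip to their assigned class by construction.
functioning_pattern_sets <- function(cutoffs = severity_cutoffs()) {
  grid <- as.matrix(expand.grid(rep(list(wg_functioning_levels), 6L),
                                stringsAsFactors = FALSE))
  colnames(grid) <- wg_functioning_domains
  cls <- classify_disability_severity(grid, cutoffs = cutoffs)
  list(patterns = grid, by_class = split(seq_len(nrow(grid)), cls))
}

# 13 per-construct affect states (never + 4 frequencies x 3 intensities) and
# the joint pairs valid for each reported affect severity under the grid.
affect_state_sets <- function(grid = default_affect_grid()) {
  freq <- c("never", rep(setdiff(wg_affect_frequencies, "never"), each = 3L))
  int <- c(NA_character_, rep(wg_affect_intensities, times = 4L))
  composite <- integer(length(freq))
  composite[1L] <- 1L
  composite[-1L] <- match(grid[cbind(freq[-1L], int[-1L])],
                          affect_composite_levels)
  joint <- expand.grid(a = seq_along(freq), d = seq_along(freq))
  joint$severity <- ifelse(pmax(composite[joint$a], composite[joint$d]) >= 3L,
                           "moderate", "none")
  list(freq = freq, int = int,
       by_class = split(seq_len(nrow(joint)), joint$severity),
       joint = joint)
}

#' Generate a synthetic survey population
#'
#' Draws, per respondent: the joint disability/affect severity class;
#' demographics from severity-conditional margins; a functioning response
#' pattern sampled uniformly from the assigned class's valid pattern set (so
#' classification round-trips exactly); affect frequency/intensity responses
#' likewise; stratum, enumeration area and dwelling selection probability from
#' the two-stage design; and the 32 raw indicator responses from the group's
#' category probabilities pushed back through the indicator configuration's
#' response maps, with refusals injected at the configured rate. Deterministic
#' given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param configs indicator configuration set; default
#'   [default_indicator_configs()].
#' @param seed overrides `scenario$seed` when given.
#' @return A data frame with one row per respondent: `respondent_id`, design
#'   fields (`province`, `stratum`, `ea`, `selection_prob`), demographics
#'   (`age`, `age_group`, `gender`, `population_group`), the six `wg_*`
#'   functioning columns, four affect columns (`anx_frequency`,
#'   `anx_intensity`, `dep_frequency`, `dep_intensity`) and 32 `ind_*` raw
#'   indicator columns. True severity classes are attached as columns
#'   `true_disability` and `true_affect` for parameter-recovery checks.
#' @export
generate_population <- function(scenario,
                                configs = default_indicator_configs(),
                                seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  n <- scenario$n
  sev_lv <- disability_severity_levels

  # joint severity class
  cells <- expand.grid(disability = sev_lv, affect = c("none", "moderate"),
                       stringsAsFactors = FALSE)
  cell_p <- as.vector(scenario$joint_severity)
  cell_id <- sample.int(nrow(cells), n, replace = TRUE, prob = cell_p)
  disability <- cells$disability[cell_id]
  affect <- cells$affect[cell_id]
  g <- match(disability, sev_lv)

  # demographics conditional on disability severity
  gender <- ifelse(stats::runif(n) < scenario$gender_male_by_severity[g],
                   "male", "female")
  age_group <- draw_by_row(scenario$age_by_severity, g)
  population_group <- draw_by_row(scenario$popgroup_by_severity, g)
  age <- integer(n)
  age[age_group == "16_24"] <- sample(16:24, sum(age_group == "16_24"), TRUE)
  age[age_group == "25_64"] <- sample(25:64, sum(age_group == "25_64"), TRUE)
  age[age_group == "65_plus"] <- sample(65:90, sum(age_group == "65_plus"), TRUE)

  # two-stage design: province x locale strata, EAs, dwelling probability
  province <- sample.int(scenario$provinces, n, replace = TRUE)
  locale <- sample(c("urban", "rural"), n, replace = TRUE)
  stratum <- paste0("p", province, "_", locale)
  ea <- paste0(stratum, "_ea", sample.int(scenario$eas_per_stratum, n, TRUE))
  selection_prob <- scenario$ea_prob[locale] * scenario$dwelling_prob[locale]

  # functioning pattern uniform within assigned class
  fsets <- functioning_pattern_sets()
  fidx <- integer(n)
  for (cl in sev_lv) {
    rows <- which(disability == cl)
    pool <- fsets$by_class[[cl]]
    fidx[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
  }
  functioning <- fsets$patterns[fidx, , drop = FALSE]
  colnames(functioning) <- paste0("wg_", wg_functioning_domains)

  # affect responses uniform within assigned class
  asets <- affect_state_sets()
  jidx <- integer(n)
  for (cl in c("none", "moderate")) {
    rows <- which(affect == cl)
    pool <- asets$by_class[[cl]]
    jidx[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
  }
  a_state <- asets$joint$a[jidx]
  d_state <- asets$joint$d[jidx]

  # indicator responses from per-group category probabilities
  ind <- draw_indicator_responses(scenario, configs, g)

  out <- data.frame(
    respondent_id = seq_len(n),
    province = province, stratum = stratum, ea = ea,
    selection_prob = unname(selection_prob),
    age = age, age_group = age_group, gender = gender,
    population_group = population_group,
    functioning,
    anx_frequency = asets$freq[a_state], anx_intensity = asets$int[a_state],
    dep_frequency = asets$freq[d_state], dep_intensity = asets$int[d_state],
    ind,
    true_disability = disability, true_affect = affect,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# categorical draw where row g of prob matrix m applies to respondent i
draw_by_row <- function(m, g) {
  u <- stats::runif(length(g))
  cum <- t(apply(m, 1L, cumsum))
  idx <- rowSums(u > cum[g, , drop = FALSE]) + 1L
  colnames(m)[idx]
}

# draw raw indicator codes for every respondent given severity group index g
draw_indicator_responses <- function(scenario, configs, g) {
  n <- length(g)
  probs <- scenario$indicator_probs   # rows: group; cols: exc, inb, inc
  rho <- scenario$latent_rho
  z_shared <- if (rho > 0) stats::rnorm(n) else NULL
  cols <- lapply(configs, function(cf) {
    p <- scenario$indicator_prob_overrides[[cf$indicator_id]]
    if (is.null(p)) p <- probs
    if (cf$mode == "binary") {   # no substantive middle code: reallocate
      p[, "excluded"] <- p[, "excluded"] +
        p[, "in_between"] * p[, "excluded"] /
          (p[, "excluded"] + p[, "included"])
      p[, "included"] <- 1 - p[, "excluded"]
      p[, "in_between"] <- 0
    }
    cum <- t(apply(p, 1L, cumsum))
    u <- if (is.null(z_shared)) stats::runif(n) else
      stats::pnorm(sqrt(rho) * z_shared + sqrt(1 - rho) * stats::rnorm(n))
    cat_idx <- rowSums(u > cum[g, , drop = FALSE]) + 1L
    code <- category_to_code(cf)[cat_idx]
    refuse <- stats::runif(n) < scenario$refusal_rate
    code[refuse] <- cf$refusal_codes[1L]
    code
  })
  out <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  names(out) <- paste0("ind_", names(configs))
  out
}

# representative raw code per inclusion category (first code mapping to it)
category_to_code <- function(cf) {
  vapply(inclusion_categories, function(cat) {
    hit <- names(cf$response_map)[cf$response_map == cat][1L]
    if (is.na(hit)) NA_character_ else hit
  }, character(1L))
}
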