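# Severity classification from the Washington Group functioning and affect items.

#' Response code sets for the functioning and affect items
#'
#' Ordinal code sets used throughout the package: the four difficulty levels of
#' the Washington Group Short Set (WG-SS) functioning questions, the six
#' functioning domains, and the frequency/intensity codes of the Extended Set
#' anxiety and depression (affect) items.
#'
#' @format Character vectors, ordered from least to most severe where the set
#'   is ordinal.
#' @name wg_codes
NULL

#' @rdname wg_codes
#' @export
wg_functioning_levels <- c("no_difficulty", "some_difficulty",
                           "a_lot_of_difficulty", "cannot_do_at_all")

#' @rdname wg_codes
#' @export
wg_functioning_domains <- c("seeing", "hearing", "walking", "cognition",
                            "self_care", "communication")

#' @rdname wg_codes
#' @export
wg_affect_frequencies <- c("never", "a_few_times_a_year", "monthly",
                           "weekly", "daily")

#' @rdname wg_codes
#' @export
wg_affect_intensities <- c("a_little", "in_between", "a_lot")

#' Disability severity levels
#'
#' The three-level classification used for reporting: \code{none < mild <
#' moderate}. Severe functioning limitation is folded into \code{moderate}.
#' @export
disability_severity_levels <- c("none", "mild", "moderate")

#' Severity cut-off configuration
#'
#' Thresholds for [classify_disability_severity()]. Under the default
#' (`variant = "extended"`) a respondent is classified `moderate` when any
#' functioning response is at or above "a lot of difficulty" **or** when five
#' or more domains are answered "some difficulty"; `mild` when two to four
#' domains are "some difficulty"; `none` otherwise. The
#' `variant = "recommended"` setting drops the five-plus "some difficulty"
#' trigger, leaving the widely used a-lot-of-difficulty cut-off only (such
#' respondents then classify as `mild`).
#'
#' @param variant `"extended"` (default) or `"recommended"`.
#' @param none_max_some maximum count of "some difficulty" still classified
#'   `none` (default 1).
#' @param mild_max_some maximum count of "some difficulty" still classified
#'   `mild` (default 4 under `"extended"`; unbounded under `"recommended"`).
#' @return A list with elements `none_max_some`, `mild_max_some`, `variant`.
#' @export
severity_cutoffs <- function(variant = c("extended", "recommended"),
                             none_max_some = 1L,
                             mild_max_some = if (match.arg(variant) == "extended") 4L else 6L) {
  variant <- match.arg(variant)
  stopifnot(none_max_some >= 0L, mild_max_some >= none_max_some)
  list(none_max_some = as.integer(none_max_some),
       mild_max_some = as.integer(mild_max_some),
       variant = variant)
}

#' Classify disability severity from the six WG-SS functioning responses
#'
#' Applies the three-branch severity rule to each respondent:
#' \itemize{
#'   \item \strong{none}: at most one domain with "some difficulty" and no
#'     response above "some difficulty";
#'   \item \strong{mild}: two to four domains with "some difficulty" and no
#'     response above it;
#'   \item \strong{moderate}: any response of "a lot of difficulty" or
#'     "cannot do at all", or five or six domains with "some difficulty".
#' }
#' Exactly one branch fires for every complete response pattern.
#'
#' @param responses A data frame or matrix with one column per functioning
#'   domain (six columns), cells drawn from [wg_functioning_levels], or a
#'   single character vector of length six for one respondent.
#' @param cutoffs Output of [severity_cutoffs()].
#' @param on_missing `"error"` (default) stops naming the first respondent and
#'   domain with a missing/refused response; `"na"` returns `NA` for such rows
#'   so the caller can drop and count them.
#' @return A factor with ordered levels `none < mild < moderate`.
#' @examples
#' classify_disability_severity(rep("no_difficulty", 6))
#' classify_disability_severity(c("some_difficulty", "some_difficulty",
#'   "some_difficulty", rep("no_difficulty", 3)))
#' @export
classify_disability_severity <- function(responses,
                                         cutoffs = severity_cutoffs(),
                                         on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  m <- as_functioning_matrix(responses)
  codes <- match(m, wg_functioning_levels)       # NA for missing/unknown
  dim(codes) <- dim(m)
  bad <- is.na(codes)
  if (any(bad)) {
    if (on_missing == "error") {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("classification undefined: missing or unrecognised functioning response ",
           "for respondent ", idx[1L], ", domain '", colnames(m)[idx[2L]], "'",
           call. = FALSE)
    }
  }
  n_some <- rowSums(codes == 2L)
  any_high <- rowSums(codes >= 3L) > 0L
  out <- rep(NA_character_, nrow(m))
  complete <- !apply(bad, 1L, any)
  moderate <- complete & (any_high | n_some > cutoffs$mild_max_some)
  mild <- complete & !moderate & n_some > cutoffs$none_max_some
  none <- complete & !moderate & !mild
  out[moderate] <- "moderate"
  out[mild] <- "mild"
  out[none] <- "none"
  factor(out, levels = disability_severity_levels, ordered = TRUE)
}

as_functioning_matrix <- function(responses) {
  if (is.atomic(responses) && is.null(dim(responses))) {
    if (length(responses) != length(wg_functioning_domains))
      stop("expected exactly six functioning responses, got ", length(responses),
           call. = FALSE)
    responses <- matrix(as.character(responses), nrow = 1L)
    colnames(responses) <- wg_functioning_domains
  }
  m <- as.matrix(responses)
  storage.mode(m) <- "character"
  if (ncol(m) != length(wg_functioning_domains))
    stop("expected six functioning columns, got ", ncol(m), call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- wg_functioning_domains
  m
}

#' Default frequency-by-intensity scoring grid for the affect composite
#'
#' Maps each (frequency, intensity) pair of an anxiety or depression item to a
#' four-level composite (`none < mild < moderate < severe`). The Washington
#' Group's own scoring of these items is unpublished work in progress, so this
#' monotone grid is a declared stand-in and fully overridable: any matrix with
#' `rownames = wg_affect_frequencies` and `colnames = wg_affect_intensities`
#' whose cells are composite levels is accepted by
#' [classify_affect_severity()].
#'
#' Default cells: severe = daily + a lot; moderate = daily + in between or
#' weekly + a lot; mild = daily + a little, weekly + a little/in between, or
#' monthly + a lot; everything else none ("never" is none at any intensity).
#'
#' @return A 5 x 3 character matrix of composite levels.
#' @export
default_affect_grid <- function() {
  g <- matrix("none", nrow = length(wg_affect_frequencies),
              ncol = length(wg_affect_intensities),
              dimnames = list(wg_affect_frequencies, wg_affect_intensities))
  g["monthly", "a_lot"] <- "mild"
  g["weekly", c("a_little", "in_between")] <- "mild"
  g["weekly", "a_lot"] <- "moderate"
  g["daily", "a_little"] <- "mild"
  g["daily", "in_between"] <- "moderate"
  g["daily", "a_lot"] <- "severe"
  g
}

affect_composite_levels <- c("none", "mild", "moderate", "severe")

#' Classify affect (psychosocial) severity from anxiety and depression items
#'
#' Each construct (anxiety, depression) is scored on a frequency-by-intensity
#' grid to a four-level composite; the respondent's composite is the maximum
#' of the two; the reported severity collapses this to two levels:
#' `moderate` when the composite is moderate or severe, `none` otherwise
#' (mild psychosocial difficulty is merged into `none`).
#'
#' Intensity is asked only when frequency is not `"never"`; an intensity value
#' alongside `frequency = "never"` is ignored, a missing intensity with any
#' other frequency is a classification error.
#'
#' @param anx_frequency,dep_frequency character vectors of frequency codes
#'   ([wg_affect_frequencies]).
#' @param anx_intensity,dep_intensity character vectors of intensity codes
#'   ([wg_affect_intensities]); may be `NA` where frequency is `"never"`.
#' @param grid scoring grid, see [default_affect_grid()].
#' @param on_missing `"error"` or `"na"` as in [classify_disability_severity()].
#' @return A factor `none < moderate` with attribute `"composite"`: the
#'   internal four-level factor it was collapsed from.
#' @examples
#' classify_affect_severity("never", NA, "never", NA)
#' classify_affect_severity("never", NA, "daily", "a_lot")
#' @export
classify_affect_severity <- function(anx_frequency, anx_intensity,
                                     dep_frequency, dep_intensity,
                                     grid = default_affect_grid(),
                                     on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  validate_affect_grid(grid)
  a <- score_construct(anx_frequency, anx_intensity, grid, "anxiety", on_missing)
  d <- score_construct(dep_frequency, dep_intensity, grid, "depression", on_missing)
  composite <- pmax(a, d)
  value <- ifelse(is.na(composite), NA_character_,
                  ifelse(composite >= 3L, "moderate", "none"))
  out <- factor(value, levels = c("none", "moderate"), ordered = TRUE)
  attr(out, "composite") <- factor(affect_composite_levels[composite],
                                   levels = affect_composite_levels,
                                   ordered = TRUE)
  out
}

validate_affect_grid <- function(grid) {
  if (!is.matrix(grid) ||
      !identical(rownames(grid), wg_affect_frequencies) ||
      !identical(colnames(grid), wg_affect_intensities) ||
      !all(grid %in% affect_composite_levels))
    stop("affect grid must be a ", length(wg_affect_frequencies), " x ",
         length(wg_affect_intensities),
         " matrix over the frequency/intensity codes with composite-level cells",
         call. = FALSE)
  invisible(grid)
}

# integer composite (1..4) per respondent for one construct
score_construct <- function(freq, int, grid, construct, on_missing) {
  n <- length(freq)
  stopifnot(length(int) == n)
  fi <- match(freq, wg_affect_frequencies)
  out <- rep(NA_integer_, n)
  never <- !is.na(fi) & freq == "never"
  out[never] <- 1L
  active <- !is.na(fi) & !never
  ii <- match(int, wg_affect_intensities)
  ok <- active & !is.na(ii)
  out[ok] <- match(grid[cbind(fi[ok], ii[ok])], affect_composite_levels)
  bad <- which(is.na(out))
  if (length(bad) && on_missing == "error") {
    what <- if (is.na(fi[bad[1L]])) "frequency" else "intensity"
    stop("classification undefined: missing or unrecognised ", construct, " ",
         what, " for respondent ", bad[1L], call. = FALSE)
  }
  out
}
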