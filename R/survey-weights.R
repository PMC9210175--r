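# Design base weights, raking to external margins, weighted proportions.

#' Design base weights from selection probabilities
#'
#' Inverse-probability weights for a stratified two-stage design. The
#' selection probability of a respondent's dwelling is the product of the
#' enumeration-area and dwelling stage probabilities; everything downstream is
#' invariant to a global rescaling of the weights, so no normalisation is
#' applied.
#'
#' @param selection_prob numeric vector of selection probabilities in (0, 1].
#' @return Numeric weight vector, `1 / selection_prob`.
#' @export
base_weights <- function(selection_prob) {
  p <- as.numeric(selection_prob)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("selection probabilities must lie in (0, 1]", call. = FALSE)
  1 / p
}

#' Margin specification for raking
#'
#' @param dimension name of the margin dimension (e.g. `"age_group"`).
#' @param shares named numeric vector of target population shares per level,
#'   nonnegative and summing to 1 (within `1e-6`).
#' @return An object of class `margin_spec`.
#' @export
margin_spec <- function(dimension, shares) {
  shares <- unlist(shares)
  if (is.null(names(shares)) || any(!nzchar(names(shares))))
    stop("margin shares must be named by level", call. = FALSE)
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-6)
    stop("margin shares for '", dimension,
         "' must be nonnegative and sum to 1", call. = FALSE)
  structure(list(dimension = dimension, shares = shares / sum(shares)),
            class = "margin_spec")
}

#' Rake weights to external population margins
#'
#' Iterative proportional fitting: cycles over the margin dimensions,
#' multiplying the weights within each level by
#' (target share x total weight) / (current level weight), until the largest
#' absolute error between any weighted margin share and its target falls below
#' `tol` or `max_iter` cycles are exhausted. Raking to shares of the running
#' total preserves the total weight.
#'
#' @param weights positive base weights (see [base_weights()]).
#' @param levels data frame with one column per margin dimension giving each
#'   respondent's level.
#' @param margins list of [margin_spec()] objects.
#' @param tol convergence tolerance on margin shares (default `1e-8`).
#' @param max_iter maximum number of full cycles (default 100). Non-convergence
#'   is reported in the metadata and by a warning, never silently.
#' @param cap optional trimming ratio: after convergence, weights above
#'   `cap x median(weights)` are trimmed to that value (off by default; the
#'   number trimmed is recorded in the metadata).
#' @return The raked numeric weight vector with attributes `iterations`,
#'   `max_margin_error`, `converged` (and `n_trimmed` when `cap` is set).
#' @export
rake_weights <- function(weights, levels, margins, tol = 1e-8, max_iter = 100L,
                         cap = NULL) {
  w <- as.numeric(weights)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  stopifnot(is.data.frame(levels), nrow(levels) == length(w))
  idx <- lapply(margins, function(m) {
    stopifnot(inherits(m, "margin_spec"))
    if (!m$dimension %in% names(levels))
      stop("levels lack margin dimension '", m$dimension, "'", call. = FALSE)
    lev <- as.character(levels[[m$dimension]])
    extra <- setdiff(unique(lev), names(m$shares))
    if (length(extra))
      stop("sample level(s) ", paste(extra, collapse = ", "),
           " missing from margin '", m$dimension, "'", call. = FALSE)
    f <- factor(lev, levels = names(m$shares))
    if (any(tabulate(f, nbins = nlevels(f)) == 0L & m$shares > 0))
      stop("raking infeasible: margin '", m$dimension, "' has a positive ",
           "target for level '",
           names(m$shares)[which(tabulate(f, nbins = nlevels(f)) == 0L &
                                   m$shares > 0)[1L]],
           "' with no sample members", call. = FALSE)
    f
  })
  margin_error <- function(w) {
    max(vapply(seq_along(margins), function(j) {
      cur <- tapply(w, idx[[j]], sum, default = 0)  # factor-level order
      max(abs(cur / sum(w) - margins[[j]]$shares))
    }, numeric(1L)))
  }
  it <- 0L
  err <- margin_error(w)
  while (err >= tol && it < max_iter) {
    for (j in seq_along(margins)) {
      total <- sum(w)
      cur <- tapply(w, idx[[j]], sum, default = 0)  # factor-level order
      ratio <- (margins[[j]]$shares * total) / cur
      ratio[!is.finite(ratio)] <- 1
      w <- w * ratio[as.integer(idx[[j]])]
    }
    it <- it + 1L
    err <- margin_error(w)
  }
  converged <- err < tol
  if (!converged)
    warning("raking did not converge in ", max_iter,
            " cycles (max margin error ", signif(err, 3), ")", call. = FALSE)
  if (!is.null(cap)) {
    lim <- cap * stats::median(w)
    n_trim <- sum(w > lim)
    w[w > lim] <- lim
    attr(w, "n_trimmed") <- n_trim
  }
  attr(w, "iterations") <- it
  attr(w, "max_margin_error") <- err
  attr(w, "converged") <- converged
  w
}

#' Weighted category proportions by group
#'
#' The share of each group's total weight falling into each inclusion
#' category, as percentages. Rows sum to 100 (before any rounding) and the
#' result is invariant to a global rescaling of the weights. Respondents with
#' `NA` category are dropped from their group's denominator; empty groups are
#' omitted with a warning.
#'
#' @param categories vector/factor of inclusion categories (NA allowed).
#' @param weights positive weights, aligned with `categories`.
#' @param groups group labels, aligned with `categories`.
#' @return A data frame: `group`, then one column per inclusion category with
#'   the weighted percentage.
#' @export
weighted_proportions <- function(categories, weights,
                                 groups = rep("all", length(categories))) {
  stopifnot(length(categories) == length(weights),
            length(groups) == length(categories))
  cat <- inclusion_factor(categories)
  keep <- !is.na(cat)
  g <- factor(groups[keep])
  tab <- tapply(weights[keep], list(g, cat[keep]), sum, default = 0)
  tab <- matrix(tab, nrow = nlevels(g),
                dimnames = list(levels(g), inclusion_categories))
  empty <- setdiff(unique(as.character(groups)), rownames(tab)[rowSums(tab) > 0])
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  pct <- 100 * (tab / rowSums(tab))
  data.frame(group = rownames(pct), as.data.frame(pct, optional = TRUE),
             row.names = NULL, check.names = FALSE)
}
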