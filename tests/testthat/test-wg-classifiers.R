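# Disability and affect severity classification.

all_functioning_patterns <- function() {
  grid <- expand.grid(rep(list(wg_functioning_levels), 6L),
                      stringsAsFactors = FALSE)
  m <- as.matrix(grid)
  colnames(m) <- wg_functioning_domains
  m
}

test_that("stated example patterns classify to their published severities", {
  pat <- function(...) c(...)
  cases <- list(
    list(pat(rep("no_difficulty", 6)), "none"),
    list(pat("some_difficulty", rep("no_difficulty", 5)), "none"),
    list(pat(rep("some_difficulty", 3), rep("no_difficulty", 3)), "mild"),
    list(pat(rep("some_difficulty", 5), "no_difficulty"), "moderate"),
    list(pat("a_lot_of_difficulty", rep("no_difficulty", 5)), "moderate"),
    list(pat("cannot_do_at_all", rep("some_difficulty", 2),
             rep("no_difficulty", 3)), "moderate")
  )
  for (cs in cases)
    expect_identical(as.character(classify_disability_severity(cs[[1]])),
                     cs[[2]])
})

test_that("all 4096 functioning patterns match the straight-line oracle with exactly one class each", {
  m <- all_functioning_patterns()
  got <- classify_disability_severity(m)
  expect_false(anyNA(got))
  want <- apply(m, 1L, oracle_disability)
  expect_identical(as.character(got), want)
  counts <- table(got)
  # frozen from the oracle: 1 + choose(6,1) none; choose(6,2..4) mild
  expect_equal(as.integer(counts), c(7L, 50L, 4039L))
  expect_identical(sum(counts), 4096L)
})

test_that("raising any single functioning response never lowers severity", {
  set.seed(42)
  m <- all_functioning_patterns()
  base <- classify_disability_severity(m)
  for (rep in 1:3) {
    i <- sample.int(6L, nrow(m), replace = TRUE)
    cur <- match(m[cbind(seq_len(nrow(m)), i)], wg_functioning_levels)
    can <- cur < 4L
    bumped <- m
    bumped[cbind(which(can), i[can])] <- wg_functioning_levels[cur[can] + 1L]
    expect_true(all(classify_disability_severity(bumped)[can] >= base[can]))
  }
})

test_that("the recommended cut-off variant drops the five-plus some-difficulty trigger", {
  five_some <- c(rep("some_difficulty", 5), "no_difficulty")
  expect_identical(
    as.character(classify_disability_severity(
      five_some, cutoffs = severity_cutoffs("recommended"))),
    "mild")
  expect_identical(
    as.character(classify_disability_severity(
      c("a_lot_of_difficulty", rep("no_difficulty", 5)),
      cutoffs = severity_cutoffs("recommended"))),
    "moderate")
})

test_that("missing functioning responses error with the domain named, or yield NA on request", {
  bad <- c("no_difficulty", NA, rep("no_difficulty", 4))
  expect_error(classify_disability_severity(bad), "hearing")
  expect_true(is.na(classify_disability_severity(bad, on_missing = "na")))
})

test_that("affect severity follows the scoring grid with max over constructs and two-level collapse", {
  # stated examples
  expect_identical(as.character(
    classify_affect_severity("never", NA, "never", NA)), "none")
  expect_identical(as.character(
    classify_affect_severity("never", NA, "daily", "a_lot")), "moderate")
  # weekly+a_little = mild, monthly+a_little = none -> max mild -> none
  r <- classify_affect_severity("weekly", "a_little", "monthly", "a_little")
  expect_identical(as.character(r), "none")
  expect_identical(as.character(attr(r, "composite")), "mild")
  # collapse consistency over every joint state
  grid <- default_affect_grid()
  freq <- c("never", rep(setdiff(wg_affect_frequencies, "never"), each = 3))
  int <- c(NA, rep(wg_affect_intensities, times = 4))
  joint <- expand.grid(a = seq_along(freq), d = seq_along(freq))
  res <- classify_affect_severity(freq[joint$a], int[joint$a],
                                  freq[joint$d], int[joint$d])
  comp <- attr(res, "composite")
  expect_identical(res == "moderate", comp >= "moderate")
})

test_that("raising affect frequency or intensity never lowers severity under the default grid", {
  comp_rank <- function(f, i)
    as.integer(attr(classify_affect_severity(f, i, "never", NA), "composite"))
  freqs <- setdiff(wg_affect_frequencies, "never")
  for (fi in seq_along(freqs))
    for (ii in seq_along(wg_affect_intensities)) {
      here <- comp_rank(freqs[fi], wg_affect_intensities[ii])
      if (fi < length(freqs))
        expect_gte(comp_rank(freqs[fi + 1], wg_affect_intensities[ii]), here)
      if (ii < length(wg_affect_intensities))
        expect_gte(comp_rank(freqs[fi], wg_affect_intensities[ii + 1]), here)
      expect_gte(here, comp_rank("never", NA))
    }
})

test_that("missing affect inputs error; intensity is required only when frequency is not never", {
  expect_error(classify_affect_severity(NA, NA, "never", NA), "frequency")
  expect_error(classify_affect_severity("weekly", NA, "never", NA), "intensity")
  expect_silent(classify_affect_severity("never", "a_lot", "never", NA))
  expect_true(is.na(classify_affect_severity("weekly", NA, "never", NA,
                                             on_missing = "na")))
})
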