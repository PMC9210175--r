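---
title: "Monitoring disability inclusion from survey microdata: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring disability inclusion from survey microdata: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inclmon)
```

## The measurement problem

Monitoring the progressive realisation of disability inclusion requires
individual-level outcome data that can be disaggregated by disability status
and severity, and by gender. `inclmon` implements such a monitoring pipeline
end to end: it classifies each survey respondent's disability and
psychosocial (affect) severity, scores their responses on a configurable set
of inclusion indicators, aggregates indicators into domain-level inclusion
categories, weights the sample to external population margins, and compares
groups with multiplicity-adjusted tests. A synthetic-microdata generator with
the same statistical structure as a national two-stage household survey makes
every stage testable without access to restricted survey data.

## Severity classification

**Disability.** The six Washington Group Short Set questions (seeing,
hearing, walking, cognition, self-care, communication) are each answered on
the four-level scale *no difficulty* < *some difficulty* < *a lot of
difficulty* < *cannot do at all*. `classify_disability_severity()` applies a
three-branch rule:

* **none** — at most one domain at *some difficulty*, nothing above it;
* **mild** — two to four domains at *some difficulty*, nothing above it;
* **moderate** — anything at *a lot of difficulty* or *cannot do at all*, or
  five or six domains at *some difficulty* (severe limitation is folded into
  this class).

The rule is total and exclusive: the test suite enumerates all $4^6 = 4096$
response patterns against an independently written straight-line oracle and
checks that exactly one branch fires for each. The five-plus
*some difficulty* trigger extends the widely used reporting cut-off; setting
`severity_cutoffs("recommended")` removes it, and both count thresholds are
plain configuration.

**Affect.** Anxiety and depression are each measured by a frequency item
(*never* … *daily*) and, when frequency is not *never*, an intensity item
(*a little*, *in between*, *a lot*). Each construct is scored on a
frequency-by-intensity grid to a four-level composite
(none < mild < moderate < severe); the respondent's composite is the maximum
over the two constructs; reporting collapses it to **none** vs **moderate**
(mild is merged into none, to separate probable psychosocial disability from
ordinary distress). The scoring grid used by the Washington Group for these
items is unpublished work in progress, so `default_affect_grid()` is a
declared stand-in — a monotone grid with *daily + a lot* = severe,
*daily + in between* or *weekly + a lot* = moderate, a mild band below that,
and everything else none. Any monotone (or non-monotone) replacement grid can
be supplied; the monotonicity property test applies to the default only.

Missing responses are never imputed: classification of an incomplete record
is undefined, and the pipeline drops such records and reports the count
(`on_missing = "na"` for vectorised use; the default errors, naming the
offending domain).

## Indicator scoring

Each of the 32 indicators maps raw response codes to the ordered trichotomy
**excluded < in between < included** through a declarative
`indicator_config()`. Fourteen indicators are *binary* — every substantive
code maps to included or excluded, and *in between* arises only from
refusals; eighteen are *nuanced*, with at least one substantive middle code
(for food security: food secure / mild-to-moderate insecurity / severe
insecurity). Refusal codes map to *in between* on every indicator.
Item-missing codes are kept distinct from refusals — a refusal is an
observed, scoreable outcome, a missing item removes the respondent from that
indicator's denominator — because the two have different statistical meaning.

The instrument's exact indicator-level cut-off definitions are not published,
so the shipped response maps are plausible reconstructions from the indicator
names: they are configuration, not code, and users supply their own maps
(directly or via `read_pipeline_config()`) to match any instrument. The
structural facts the aggregation relies on — 32 indicators, the 14/18 split,
and the 4/12/2/2/2/2/3/1/4 partition over the nine domains — are validated at
load time.

## Domain aggregation

Domains aggregate their indicators with a dual cut-off $k$-of-$n$ rule
(`aggregate_domain()`): a domain is **included** when at least $k$ indicators
are included *and* none of the rest is excluded; **excluded** when at least
$k$ are excluded *and* none of the rest is included; **in between**
otherwise. The thresholds are $k = 1, 1, 2, 3, 8$ for $n = 1, 2, 3, 4, 12$ —
a sequence that fits no clean closed form, so it is stored per domain size in
configuration rather than derived. The suite enumerates all $3^n$ patterns
(including $3^{12} = 531{,}441$ for the twelve-indicator living-conditions
domain) against a straight-line oracle of the rule text, and checks
exclusivity of the two extreme branches, the included/excluded symmetry, and
monotonicity in every single indicator. A respondent missing any indicator
within a domain gets a missing domain result and leaves that domain's
denominator; the source analysis does not describe within-domain
missingness, so this conservative choice is the package's own.

## Weighting

Base weights are inverse dwelling selection probabilities (product of the
enumeration-area and dwelling stage probabilities of the stratified two-stage
design). `rake_weights()` then performs iterative proportional fitting to
external margins — by default age group (16–24 / 25–64 / 65+), gender and
population group — cycling over dimensions and rescaling each level's weight
share toward its target until the largest margin error is below `tol`.
Numerical choices: `tol = 1e-8` on margin shares and `max_iter = 100` cycles,
both exposed; non-convergence is recorded in the weight metadata and raised
as a warning, never silent; an empty sample cell with a positive target is an
error naming the level. Raking to shares of the running total preserves total
weight, and everything downstream is invariant to a global rescaling. No
weight trimming is applied by default; a cap ratio is available and its
effect logged. The default margin values in `default_margins()` are plausible
national adult shares used for calibration of the synthetic scenario —
replace them with real census margins for substantive use.

## Group comparisons

Tables compare weighted category percentages across severity-by-gender
groups (six groups for disability, four for affect). The default test,
`pearson_effective_n`, rescales the weighted contingency table so its total
equals the Kish effective sample size $(\sum w)^2 / \sum w^2$ and applies the
Pearson chi-squared statistic — a transparent first-order correction for
unequal weighting. A `rao_scott` flavour rescales each group's row by that
group's own effective size. The source analysis does not state its
chi-squared variant, so the simple, reproducible default was chosen and both
are flags.

Two reference-distribution details matter in practice:

* **Sparse cells.** Some inclusion categories are rare (domain-level
  exclusion can be nearly impossible under the dual cut-off), so expected
  counts below 1 occur in small groups and make the asymptotic chi-squared
  reference anti-conservative. With `exact = "auto"` (default) the p-value
  switches to the Monte Carlo conditional-on-margins distribution of the
  statistic (as in `chisq.test(simulate.p.value = TRUE)`, $B = 2000$)
  whenever any expected rescaled count falls below 5 (Cochran's rule). This
  restores type-I calibration in simulation; `"never"` and `"always"` are
  available. Monte Carlo p-values consume the R random stream, so seeded runs
  (the pipeline always seeds when given a scenario) are exactly reproducible.
* **Degenerate tables.** Categories observed in no group are dropped before
  testing; a table reduced below 2 × 2 has no defined test and is reported as
  not-available rather than a number.

Raw p-values are Bonferroni-adjusted, $p_{adj} = \min(1, m \cdot p)$, with
$m$ defaulting to the family size (9 for the domain family, 32 for the
indicator family); the source analysis never states its $m$, so it is a
configuration option. Family-wise type-I error under the null and power for
a planted single-domain effect are estimated by `simulate_type1()` /
`simulate_rejections()`, which hold the generated population's design and
group labels fixed and redraw only the indicator outcomes — exactly the null
(or alternative) hypothesis of the homogeneity tests.

## The synthetic generator

`synthetic_scenario()` encodes the study conditions the pipeline assumes;
`generate_population()` draws from them. Defaults are calibrated to the
published scale of a national disability-inclusion survey: $n = 8499$; a
joint disability-by-affect severity table normalised from
66.6/6.8/6.8 // 13.7/2.7/3.5 percent (margins ≈ 80/10/10 disability,
80/20 affect); women over-represented at higher severity (male share
0.497/0.347/0.306 by severity); severity-skewed age and population-group
margins; nine provinces × urban/rural strata with different stage-selection
probabilities (so base weights genuinely vary); and a 0.5% refusal rate.
Functioning and affect response patterns are drawn uniformly from the
assigned class's valid pattern set — constructed from the classifier's own
partition, so generated records round-trip to their class with probability 1;
a configurable within-class distribution can replace the uniform since no
pattern-level detail is published. Indicator categories are drawn
independently across indicators given the severity group, with inclusion
declining in severity by default (0.70/0.55/0.50); per-indicator overrides
plant effects in chosen domains, and a shared-latent-propensity hook
(`latent_rho`) induces within-respondent correlation for sensitivity work but
defaults off for transparency.

What the generator deliberately does **not** emulate: within-respondent
correlation between deprivations (off by default), spatial clustering of
outcomes within enumeration areas, age- or population-group-conditional
indicator probabilities, and item-missingness mechanisms other than uniform
refusal. Passing tests therefore demonstrate the correctness of the
machinery under a known, well-behaved generative model — not that any real
population satisfies that model.

Demographics are drawn conditional on disability severity only; the
affect-conditional demographic skews of the source tables are induced
indirectly through the joint severity table rather than matched exactly.

## Gaps, patterns, prioritisation

`compute_gaps()` reports male-minus-female differences in inclusion (domains)
or exclusion (indicators) per severity class, naming the worse-off gender.
`classify_severity_pattern()` labels each indicator's exclusion profile over
the three severity classes: not significant (adjusted p ≥ α), monotone
worsening, mild-equals-moderate-worse (within a 2-point closeness band, both
above none), or the residual mild-worst / none-worst orderings.
`prioritise_domains()` ranks domains under three targeting approaches:
closest to inclusion (highest inclusion below a configurable ceiling,
preferring large in-between mass), farthest from inclusion (lowest inclusion,
or highest exclusion by flag), and largest disability gap (inclusion of the
no-disability class minus the pooled with-disability classes). Ties break
alphabetically and are flagged. Because the published tables carry
percentages but not group sizes, gender pooling uses equal pooling weights
unless group weights are supplied.

## Problem sizes and runtime choices

The test suite enumerates the full $4^6$ and $3^n$ ($n \le 12$) pattern
spaces exactly; samples 6,000 functioning and 4,500 domain monotonicity
cases; verifies the weighted test against the classical Pearson p-value on
100 unit-weight tables at $10^{-10}$; estimates family-wise type-I error
from 500 null replicates at $n = 5000$; and runs parameter recovery at
$n = 10{,}000$ with 3-standard-error bands. The acceptance script re-runs
the calibrated pipeline at $n = 8499$ and the null simulation at 300
replicates. These sizes were chosen to make Monte Carlo bands tight enough
to be informative while keeping a full run to a few minutes.

## Known limitations

* The default response maps and the binary/nuanced split are reconstructions;
  results on real data require instrument-matched configuration.
* The affect scoring grid is a stand-in for unpublished scoring work.
* The effective-sample-size correction treats weights as independent of
  outcomes and ignores cluster-level correlation; with strong intra-cluster
  correlation a full design-based variance estimator would be needed.
* The dual cut-off thresholds are taken as given; sensitivity analysis of
  the cut-offs is exposed via configuration but not automated.
* Raking assumes margin levels are observed in-sample; very sparse
  subpopulations may require collapsed margin levels.
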